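# Minimal PLY support for point clouds with arbitrary per-vertex scalar
# properties. Reads ascii and binary_little_endian; writes
# binary_little_endian. Only the "vertex" element is used.

.ply_sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_header <- function(con) {
  if (readLines(con, n = 1L) != "ply") stop("not a PLY file (missing magic)")
  fmt <- NULL; elements <- list(); cur <- NULL; comments <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "comment") comments <- c(comments, paste(tok[-1], collapse = " "))
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              names = character(), types = character())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") stop("PLY list properties are not supported")
      elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
      elements[[cur]]$names <- c(elements[[cur]]$names, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  list(format = fmt, elements = elements, comments = comments)
}

.ply_read_binary_element <- function(con, el) {
  sizes <- .ply_sizes[el$types]
  if (anyNA(sizes)) stop("unknown PLY property type")
  rec <- sum(sizes)
  n <- el$count
  payload <- readBin(con, "raw", n = rec * n)
  if (length(payload) < rec * n) stop("truncated PLY payload")
  off <- cumsum(c(0L, sizes))[seq_along(sizes)]
  out <- vector("list", length(el$names))
  names(out) <- el$names
  base <- (seq_len(n) - 1L) * rec
  for (k in seq_along(el$names)) {
    s <- sizes[k]; ty <- el$types[k]
    idx <- rep(base, each = s) + off[k] + seq_len(s)
    bytes <- payload[idx]
    out[[k]] <- switch(ty,
      char = , int8 = readBin(bytes, "integer", n = n, size = 1L, signed = TRUE),
      uchar = , uint8 = as.integer(bytes),
      short = , int16 = readBin(bytes, "integer", n = n, size = 2L,
                                signed = TRUE, endian = "little"),
      ushort = , uint16 = readBin(bytes, "integer", n = n, size = 2L,
                                  signed = FALSE, endian = "little"),
      int = , int32 = , uint = , uint32 =
        readBin(bytes, "integer", n = n, size = 4L, endian = "little"),
      float = , float32 = readBin(bytes, "numeric", n = n, size = 4L,
                                  endian = "little"),
      double = , float64 = readBin(bytes, "numeric", n = n, size = 8L,
                                   endian = "little"))
  }
  as.data.frame(out, optional = TRUE)
}

.ply_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .ply_read_header(con)
  if (!"vertex" %in% names(hdr$elements))
    stop("PLY file has no vertex element")
  if (names(hdr$elements)[1] != "vertex")
    stop("vertex must be the first PLY element")
  el <- hdr$elements[["vertex"]]
  df <- if (hdr$format == "ascii") {
    lines <- readLines(con, n = el$count)
    if (length(lines) < el$count) stop("truncated PLY payload")
    m <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                nrow = el$count, byrow = TRUE)
    colnames(m) <- el$names
    as.data.frame(m)
  } else {
    .ply_read_binary_element(con, el)
  }
  attr(df, "ply_comments") <- hdr$comments
  df
}

# cols: data.frame; types: named character vector of PLY types per column
.ply_write <- function(cols, types, path, comments = character()) {
  n <- nrow(cols)
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("comment", comments),
           sprintf("element vertex %d", n),
           sprintf("property %s %s", types[names(cols)], names(cols)),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  sizes <- .ply_sizes[types[names(cols)]]
  rec <- sum(sizes)
  off <- cumsum(c(0L, sizes))[seq_along(sizes)]
  payload <- raw(rec * n)
  base <- (seq_len(n) - 1L) * rec
  for (k in seq_along(cols)) {
    ty <- types[[names(cols)[k]]]; s <- sizes[k]
    bytes <- switch(ty,
      uchar = , uint8 = as.raw(as.integer(cols[[k]])),
      int = , int32 = writeBin(as.integer(cols[[k]]), raw(),
                               size = 4L, endian = "little"),
      float = , float32 = writeBin(as.numeric(cols[[k]]), raw(),
                                   size = 4L, endian = "little"),
      double = , float64 = writeBin(as.numeric(cols[[k]]), raw(),
                                    size = 8L, endian = "little"),
      stop("unsupported PLY write type: ", ty))
    if (n) payload[rep(base, each = s) + off[k] + seq_len(s)] <- bytes
  }
  writeBin(payload, con)
  invisible(NULL)
}
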