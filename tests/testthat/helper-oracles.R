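# Independent brute-force oracles, coded directly from the defining
# formulas with explicit loops. They deliberately share no code with the
# package internals they check.

oracle_calibrate <- function(vt, vb, rb) {
  out <- matrix(NA_real_, nrow(vt), ncol(vt))
  for (i in seq_len(nrow(vt)))
    for (j in seq_len(ncol(vt)))
      out[i, j] <- vt[i, j] / vb[j] * rb[j]
  out
}

# channel index on the 550-1050/5 grid, 1-based
oracle_chan <- function(w) (w - 550) / 5 + 1

oracle_features <- function(sp) {
  out <- matrix(NA_real_, nrow(sp), 9)
  colnames(out) <- c("R700", "R730", "R780", "R850", "R900",
                     "AVG_R760_R930", "CI_red_edge", "NDVI", "NDRE")
  for (i in seq_len(nrow(sp))) {
    s <- sp[i, ]
    r <- function(w) s[oracle_chan(w)]
    avg <- mean(s[oracle_chan(760):oracle_chan(930)])
    out[i, ] <- c(r(700), r(730), r(780), r(850), r(900), avg,
                  r(780) / r(710) - 1,
                  (r(800) - r(670)) / (r(800) + r(670)),
                  (r(790) - r(720)) / (r(790) + r(720)))
  }
  out
}

oracle_dist <- function(xyz) {
  n <- nrow(xyz)
  S <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      S[i, j] <- sqrt((xyz[i, 1] - xyz[j, 1])^2 +
                      (xyz[i, 2] - xyz[j, 2])^2 +
                      (xyz[i, 3] - xyz[j, 3])^2)
  S
}

# full-sort nearest neighbors: sort every row of the complete distance
# matrix (ties to lower index), drop self, take N
oracle_knn <- function(xyz, N) {
  S <- oracle_dist(xyz)
  n <- nrow(S)
  idx <- matrix(NA_integer_, n, N)
  for (k in seq_len(n)) {
    o <- order(S[k, ])
    o <- o[o != k]
    idx[k, ] <- o[seq_len(N)]
  }
  idx
}

# hand-count scoring: T_j / H_j per class, overall = sum T / sum H
oracle_score <- function(pred, truth) {
  classes <- c("UnripeFruit", "RipeFruit", "Wood", "Leaf")
  Tj <- Hj <- setNames(numeric(4), classes)
  for (i in seq_along(truth)) {
    Hj[truth[i]] <- Hj[truth[i]] + 1
    if (pred[i] == truth[i]) Tj[truth[i]] <- Tj[truth[i]] + 1
  }
  Kj <- ifelse(Hj > 0, Tj / Hj, NA_real_)
  list(Tj = Tj, Hj = Hj, Kj = Kj, overall = sum(Tj) / sum(Hj))
}

# step-by-step sequential reprogramming trace: visit points in index
# order, recompute the k-th point's N nearest others from scratch, take
# the plurality of current labels, keep the current label on a tie it
# participates in, and rewrite immediately
oracle_reprogram_seq <- function(xyz, labels, N) {
  classes <- c("UnripeFruit", "RipeFruit", "Wood", "Leaf")
  cur <- as.character(labels)
  n <- nrow(xyz)
  for (k in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n))
      d[j] <- sqrt(sum((xyz[k, ] - xyz[j, ])^2))
    o <- order(d)
    o <- o[o != k][seq_len(N)]
    counts <- setNames(numeric(4), classes)
    for (j in o) counts[cur[j]] <- counts[cur[j]] + 1
    top <- classes[counts == max(counts)]
    if (length(top) == 1L) cur[k] <- top
    else if (!cur[k] %in% top) {
      for (j in o) if (cur[j] %in% top) { cur[k] <- cur[j]; break }
    }
  }
  cur
}

# minimal independent PLY reader (binary little-endian, scalar properties
# only): reads one vertex at a time, property by property
oracle_read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  stopifnot(readLines(con, n = 1) == "ply")
  nms <- c(); typs <- c(); nv <- NA
  repeat {
    ln <- readLines(con, n = 1)
    tk <- strsplit(ln, " ")[[1]]
    if (tk[1] == "element") nv <- as.integer(tk[3])
    if (tk[1] == "property") { typs <- c(typs, tk[2]); nms <- c(nms, tk[3]) }
    if (tk[1] == "end_header") break
  }
  out <- matrix(NA_real_, nv, length(nms), dimnames = list(NULL, nms))
  for (v in seq_len(nv))
    for (p in seq_along(nms))
      out[v, p] <- switch(typs[p],
        double = readBin(con, "numeric", 1, size = 8, endian = "little"),
        float = readBin(con, "numeric", 1, size = 4, endian = "little"),
        uchar = as.integer(readBin(con, "raw", 1)),
        stop("type"))
  out
}
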