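# Independent oracle implementations used to cross-check package results.

# Flood-fill connected components over a point set: two points connect
# when their Euclidean distance is <= eps. Returns component labels.
flood_fill_components <- function(points, eps) {
  n <- nrow(points)
  if (!n) return(integer(0))
  D <- as.matrix(stats::dist(points))
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i]) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (labels[cur]) next
      labels[cur] <- cl
      queue <- c(queue, which(D[cur, ] <= eps & labels == 0L))
    }
  }
  labels
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}

# Flood-fill clustering of a channel x time logical mask under a channel
# adjacency graph (plus consecutive-time neighborhood). Returns a list of
# sorted "ch.t" member key vectors, one per component.
mask_components <- function(mask, adj) {
  C <- nrow(mask); Tn <- ncol(mask)
  lab <- matrix(0L, C, Tn)
  cl <- 0L
  for (c0 in seq_len(C)) for (t0 in seq_len(Tn)) {
    if (!mask[c0, t0] || lab[c0, t0]) next
    cl <- cl + 1L
    queue <- list(c(c0, t0))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      ch <- cur[1]; tt <- cur[2]
      if (!mask[ch, tt] || lab[ch, tt]) next
      lab[ch, tt] <- cl
      for (tn in c(tt - 1, tt + 1))
        if (tn >= 1 && tn <= Tn && mask[ch, tn] && !lab[ch, tn])
          queue <- c(queue, list(c(ch, tn)))
      for (cn in which(adj[ch, ]))
        if (mask[cn, tt] && !lab[cn, tt])
          queue <- c(queue, list(c(cn, tt)))
    }
  }
  lapply(seq_len(cl), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    sort(paste(idx[, 1], idx[, 2], sep = "."))
  })
}
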