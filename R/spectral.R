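#' Epoch continuous data around markers, with overlap allowed
#'
#' Extracts a 4-s window centered on each marker so that spectral
#' estimates can be computed on the full window and the outer second on
#' each side discarded, leaving an analysis axis of -1..+1 s around the
#' marker (both endpoints included). Markers closer than 2 s to either
#' recording edge are dropped; the count of dropped markers is logged and
#' stored. Windows of neighboring markers may overlap.
#'
#' @param continuous a [ts_set()].
#' @param markers marker times in seconds.
#' @return object of class `epoch_set`: `data`
#'   (trials x channels x samples, -1..+1 s), `pad_data` (the full
#'   -2..+2 s windows used for spectral estimation), `times`, `pad_times`,
#'   `sampling_rate`, `channels`, `n_dropped`.
#' @export
epoch_with_overlap <- function(continuous, markers) {
  stopifnot(inherits(continuous, "ts_set"))
  sf <- continuous$sampling_rate
  T_ <- n_samples(continuous); C <- n_channels(continuous)
  half_out <- round(2 * sf); half_in <- round(1 * sf)
  centers <- round(markers * sf) + 1
  ok <- centers - half_out >= 1 & centers + half_out <= T_
  n_drop <- sum(!ok)
  if (n_drop)
    message(n_drop, " marker(s) closer than 2 s to a recording edge dropped")
  centers <- centers[ok]
  if (!length(centers)) stop("no marker far enough from the edges")
  n_pad <- 2 * half_out + 1; n_in <- 2 * half_in + 1
  pad <- array(0, c(length(centers), C, n_pad))
  for (i in seq_along(centers))
    pad[i, , ] <- continuous$data[, (centers[i] - half_out):(centers[i] + half_out)]
  inner <- (half_out - half_in + 1):(half_out + half_in + 1)
  structure(
    list(data = pad[, , inner, drop = FALSE], pad_data = pad,
         times = (-half_in:half_in) / sf,
         pad_times = (-half_out:half_out) / sf,
         sampling_rate = sf, channels = continuous$channels,
         n_dropped = n_drop),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%.2g..%.2g s) @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$sampling_rate))
  invisible(x)
}

#' Build an epoch set directly from a trials x channels x samples array
#'
#' For simulated data that is already epoched. The time axis is centered
#' on 0.
#'
#' @param arr numeric array trials x channels x samples.
#' @param sampling_rate Hz.
#' @param channels optional channel names.
#' @return an `epoch_set` (with `pad_data` equal to `data`).
#' @export
epoch_set_from_array <- function(arr, sampling_rate, channels = NULL) {
  stopifnot(length(dim(arr)) == 3)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(arr)[2]))
  ns <- dim(arr)[3]
  times <- (seq_len(ns) - (ns + 1) / 2) / sampling_rate
  structure(
    list(data = arr, pad_data = arr, times = times, pad_times = times,
         sampling_rate = sampling_rate, channels = channels, n_dropped = 0L),
    class = "epoch_set")
}

# Complex Morlet wavelet at frequency f: Gaussian envelope with SD
# sigma_t = cycles/(2 pi f), truncated at +/- 3 sigma_t, unit energy.
morlet_wavelet <- function(f, cycles, sf) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(3 * sigma_t * sf)
  t <- (-half:half) / sf
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet time-frequency power
#'
#' Convolves each trial and channel with complex Morlet wavelets on a
#' 3-30 Hz grid. The number of cycles grows linearly from 3 (at 3 Hz) to
#' 12 (at 30 Hz); the Gaussian envelope is truncated at three standard
#' deviations. Convolution runs on the padded -2..+2 s window when the
#' epochs carry one, and the returned power covers only the central
#' -1..+1 s, so filter edge effects stay outside the analysis axis.
#' Power is the squared magnitude of the complex coefficients (relative
#' units), averaged over trials.
#'
#' @param epochs an `epoch_set`.
#' @param freqs frequency grid in Hz, default `3:30` (1-Hz steps).
#' @return object of class `tfr_result`: `power`
#'   (channels x frequencies x times), `freqs`, `times`, `bands`
#'   (theta 4-7, alpha 8-12, beta 15-30 Hz masks), `n_trials`.
#' @export
morlet_tfr <- function(epochs, freqs = 3:30) {
  stopifnot(inherits(epochs, "epoch_set"))
  sf <- epochs$sampling_rate
  if (sf < 2 * max(freqs))
    stop("frequency grid extends beyond the Nyquist frequency")
  pad <- epochs$pad_data
  n_tr <- dim(pad)[1]; C <- dim(pad)[2]; Lp <- dim(pad)[3]
  keep <- match(round(epochs$times * sf), round(epochs$pad_times * sf))
  nt <- length(keep)
  cyc <- 3 + (freqs - 3) * (12 - 3) / (30 - 3)
  pow <- array(0, c(C, length(freqs), nt))
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], cyc[fi], sf)
    Lw <- length(w); half <- (Lw - 1) / 2
    nfft <- stats::nextn(Lp + Lw - 1, 2)
    Wf <- stats::fft(c(w, rep(0, nfft - Lw)))
    for (tr in seq_len(n_tr)) {
      for (ch in seq_len(C)) {
        Xf <- stats::fft(c(pad[tr, ch, ], rep(0, nfft - Lp)))
        conv <- stats::fft(Xf * Wf, inverse = TRUE) / nfft
        centered <- conv[half + seq_len(Lp)]   # align to input samples
        pow[ch, fi, ] <- pow[ch, fi, ] + Mod(centered[keep])^2
      }
    }
  }
  structure(
    list(power = pow / n_tr, freqs = freqs, times = epochs$times,
         bands = list(theta = c(4, 7), alpha = c(8, 12), beta = c(15, 30)),
         n_trials = n_tr),
    class = "tfr_result")
}

#' Average time-frequency power over a frequency band
#'
#' @param tfr a `tfr_result`.
#' @param band band name (`"theta"`, `"alpha"`, `"beta"`) or numeric
#'   `c(low, high)` in Hz.
#' @return channels x times matrix of band-averaged power.
#' @export
band_power <- function(tfr, band) {
  stopifnot(inherits(tfr, "tfr_result"))
  if (is.character(band)) band <- tfr$bands[[match.arg(band, names(tfr$bands))]]
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency-grid points")
  apply(tfr$power[, sel, , drop = FALSE], c(1, 3), mean)
}

#' Read a channel adjacency graph from JSON
#'
#' Expected shape: `{"channels": [...], "edges": [[a, b], ...]}` with
#' edges naming channel pairs.
#'
#' @param path JSON path.
#' @return symmetric logical adjacency matrix with channel dimnames.
#' @export
read_adjacency <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  adjacency_matrix(obj$channels, obj$edges)
}

#' Build a channel adjacency matrix from an edge list
#' @param channels character vector of channel names.
#' @param edges two-column matrix or list of length-2 vectors of channel
#'   names (or indices).
#' @return symmetric logical adjacency matrix.
#' @export
adjacency_matrix <- function(channels, edges) {
  C <- length(channels)
  A <- matrix(FALSE, C, C, dimnames = list(channels, channels))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  if (!is.null(edges) && length(edges)) {
    if (is.character(edges)) {
      i <- match(edges[, 1], channels); j <- match(edges[, 2], channels)
    } else { i <- edges[, 1]; j <- edges[, 2] }
    if (anyNA(i) || anyNA(j)) stop("edge names a channel not in 'channels'")
    A[cbind(i, j)] <- TRUE; A[cbind(j, i)] <- TRUE
  }
  A
}

# Connected components of a suprathreshold channel x time mask.
# Neighbors: consecutive time points within a channel, adjacent channels
# at the same time point. Returns a list of index matrices (channel, time).
supra_clusters <- function(mask, adj) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  C <- nrow(mask); Tn <- ncol(mask)
  key <- (idx[, 2] - 1L) * C + idx[, 1]
  inset <- logical(C * Tn); inset[key] <- TRUE
  visited <- logical(C * Tn)
  comps <- list()
  nbrs_of <- lapply(seq_len(C), function(ch) which(adj[ch, ]))
  for (start in key) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE; members <- integer()
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      ch <- (cur - 1L) %% C + 1L; tt <- (cur - 1L) %/% C + 1L
      cand <- integer()
      if (tt > 1) cand <- c(cand, cur - C)
      if (tt < Tn) cand <- c(cand, cur + C)
      nb <- nbrs_of[[ch]]
      if (length(nb)) cand <- c(cand, (tt - 1L) * C + nb)
      cand <- cand[inset[cand] & !visited[cand]]
      visited[cand] <- TRUE
      queue <- c(queue, cand)
    }
    comps[[length(comps) + 1L]] <-
      cbind(channel = (members - 1L) %% C + 1L,
            time = (members - 1L) %/% C + 1L)
  }
  comps
}

# Pooled-variance two-sample t map over channel x time cells.
# a, b: subjects x cells matrices. Returns the t vector.
tmap_pooled <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(a^2) - na * ma^2
  vb <- colSums(b^2) - nb * mb^2
  sp2 <- (va + vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Spatiotemporal cluster-based permutation test
#'
#' Compares per-subject channel x time band-power maps between two groups
#' while controlling the multiple-comparison problem over space and time.
#' Per (channel, time) cell an independent-samples pooled t is computed;
#' cells with two-sided `p < sample_alpha` and the same sign are grouped
#' into connected clusters (channel neighbors per the adjacency graph,
#' consecutive time points) of at least `min_cluster_size` cells. Each
#' cluster's mass is its summed t. The Monte-Carlo reference distribution
#' is built from `n_perm` random subject-level relabelings using the
#' maximum cluster mass per sign (the observed labeling is included in
#' the null count); clusters with `p < cluster_alpha` are flagged.
#'
#' @param group_a,group_b numeric arrays, subjects x channels x times.
#' @param adjacency symmetric logical channel adjacency matrix covering
#'   all channels (see [adjacency_matrix()]).
#' @param n_perm number of random relabelings (default 1000).
#' @param sample_alpha cell-level threshold (default 0.05, two-sided).
#' @param cluster_alpha cluster significance level (default 0.0025).
#' @param min_cluster_size minimum cells per cluster (default 2).
#' @param seed integer seed for the relabelings.
#' @return object of class `cluster_test_result`: `clusters` (each with
#'   `members`, `polarity`, `mass`, `p`, `significant`), `tmap`,
#'   `n_permutations`, and the thresholds used.
#' @export
cluster_permutation_test <- function(group_a, group_b, adjacency,
                                     n_perm = 1000, sample_alpha = 0.05,
                                     cluster_alpha = 0.0025,
                                     min_cluster_size = 2, seed = 1) {
  stopifnot(length(dim(group_a)) == 3, length(dim(group_b)) == 3)
  C <- dim(group_a)[2]; Tn <- dim(group_a)[3]
  if (!identical(dim(group_b)[2:3], dim(group_a)[2:3]))
    stop("groups must share the channel x time grid")
  if (dim(group_a)[1] < 2 || dim(group_b)[1] < 2)
    stop("need at least 2 subjects per group")
  if (nrow(adjacency) != C)
    stop("adjacency must cover all channels")
  comp_cover <- supra_clusters(matrix(TRUE, C, 1), adjacency)
  if (length(comp_cover) > 1)
    warning("adjacency graph is disconnected (",
            length(comp_cover), " components)")
  na <- dim(group_a)[1]; nb <- dim(group_b)[1]
  Xa <- matrix(group_a, na, C * Tn)
  Xb <- matrix(group_b, nb, C * Tn)
  X <- rbind(Xa, Xb)
  df <- na + nb - 2
  tcrit <- stats::qt(1 - sample_alpha / 2, df)

  cluster_stats <- function(tv) {
    tm <- matrix(tv, C, Tn)
    out <- list()
    for (pol in c(1, -1)) {
      mask <- (pol * tm) > tcrit
      for (cl in supra_clusters(mask, adjacency)) {
        if (nrow(cl) < min_cluster_size) next
        out[[length(out) + 1L]] <- list(
          members = cl, polarity = pol, mass = sum(tm[cl]))
      }
    }
    out
  }

  t_obs <- tmap_pooled(Xa, Xb)
  obs <- cluster_stats(t_obs)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  max_pos <- numeric(n_perm); max_neg <- numeric(n_perm)
  n_tot <- na + nb
  for (r in seq_len(n_perm)) {
    idx <- sample.int(n_tot, na)
    tv <- tmap_pooled(X[idx, , drop = FALSE], X[-idx, , drop = FALSE])
    cs <- cluster_stats(tv)
    if (length(cs)) {
      masses <- vapply(cs, `[[`, numeric(1), "mass")
      max_pos[r] <- max(c(masses[masses > 0], 0))
      max_neg[r] <- min(c(masses[masses < 0], 0))
    }
  }
  clusters <- lapply(obs, function(cl) {
    p <- if (cl$polarity > 0)
      (1 + sum(max_pos >= cl$mass)) / (n_perm + 1)
    else
      (1 + sum(max_neg <= cl$mass)) / (n_perm + 1)
    c(cl, list(p = p, significant = p < cluster_alpha))
  })
  structure(
    list(clusters = clusters, tmap = matrix(t_obs, C, Tn),
         n_permutations = n_perm, sample_alpha = sample_alpha,
         cluster_alpha = cluster_alpha,
         min_cluster_size = min_cluster_size),
    class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_permutations))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d cells, mass %.2f, p = %.4f%s\n",
                if (cl$polarity > 0) "positive" else "negative",
                nrow(cl$members), cl$mass, cl$p,
                if (cl$significant) " *" else ""))
  invisible(x)
}
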