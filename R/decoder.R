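#' Decoder configuration
#'
#' Settings for the binarized-Bernoulli naive-Bayes decoder of joint
#' (position bin, corridor): an 11-frame uniform smoothing kernel applied as
#' a moving sum before binarization at 0.5 (so any inferred event within the
#' window marks the frame as spiking), removal of gray-zone frames, laps
#' shorter than 40 frames, frames slower than 3 cm/s and the first 2% of the
#' track, 50 bins per corridor, up to 400 neurons per decoder averaged over
#' 20 independent subsamples, 10-fold cross-validation on contiguous frame
#' blocks, and a Jeffreys-style pseudocount on the spike probabilities.
#'
#' @param smooth_frames uniform kernel length (default 11).
#' @param binarize_threshold threshold on the smoothed activity (default 0.5).
#' @param min_lap_frames laps with fewer frames are dropped (default 40).
#' @param v_min_decoding frames slower than this are dropped, cm/s
#'   (default 3; frames at exactly the floor are kept).
#' @param skip_track_fraction leading fraction of the corridor omitted
#'   (default 0.02, i.e. the first of 50 bins).
#' @param n_neurons neurons per decoder subsample (default 400).
#' @param n_subsamples independent neuron subsamples averaged (default 20).
#' @param folds cross-validation folds (default 10).
#' @param pseudocount added to spike/no-spike counts (default 0.5; 0 is
#'   rejected because zero-probability states break the log-likelihood).
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(smooth_frames = 11, binarize_threshold = 0.5,
                           min_lap_frames = 40, v_min_decoding = 3,
                           skip_track_fraction = 0.02,
                           n_neurons = 400, n_subsamples = 20, folds = 10,
                           pseudocount = 0.5) {
  stopifnot(smooth_frames >= 1, min_lap_frames >= 1, folds >= 2,
            n_neurons >= 1, n_subsamples >= 1, v_min_decoding >= 0)
  if (pseudocount <= 0)
    stop("pseudocount must be positive (zero-probability states are not decodable)")
  structure(as.list(environment()), class = "decoder_config")
}

# centered moving sum with truncated windows at the trace ends
moving_sum <- function(x, k) {
  half <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (k - 1 - half), n)
  cs[hi + 1] - cs[lo]
}

#' Prepare a session for decoding
#'
#' Removes gray-zone frames, laps shorter than `min_lap_frames`, frames
#' below the speed floor and the first `skip_track_fraction` of the track;
#' smooths each cell's inferred spikes with the uniform kernel and binarizes
#' at the threshold.
#'
#' @param s a `corridor_session`.
#' @param cfg a [decoder_config()].
#' @return list: `B` (binary matrix cells x retained frames), `bin` (0-based
#'   bin), `corridor`, `lap`, `frame` (original frame index).
#' @export
preprocess_for_decoding <- function(s, cfg = decoder_config()) {
  keep <- s$corridor != GRAY
  lt <- segment_laps(s)
  short <- lt$lap_index[lt$n_frames < cfg$min_lap_frames]
  keep <- keep & !(s$lap %in% short)
  keep <- keep & s$speed >= cfg$v_min_decoding
  b0 <- rep(NA_integer_, n_frames(s))
  ng <- s$corridor != GRAY
  b0[ng] <- bin_position(s$position[ng], s$corridor_length, s$n_bins)
  skip_bins <- floor(cfg$skip_track_fraction * s$n_bins)
  keep <- keep & !is.na(b0) & b0 >= skip_bins
  if (!any(keep)) stop("no frames retained after decoding filters")
  sm <- t(apply(s$spikes, 1, moving_sum, k = cfg$smooth_frames))
  B <- (sm > cfg$binarize_threshold) * 1L
  idx <- which(keep)
  list(B = B[, idx, drop = FALSE], bin = b0[idx], corridor = s$corridor[idx],
       lap = s$lap[idx], frame = idx)
}

#' Fit the Bernoulli naive-Bayes decoder
#'
#' `P(s_i | x_j, c_k)` is the fraction of training frames in state (bin j,
#' corridor k) in which neuron i spiked, regularized as
#' `(spike frames + pseudocount) / (T_jk + 2 * pseudocount)`. States with no
#' training frames are flagged unusable and excluded from the posterior
#' support.
#'
#' @param B binary spike matrix, cells x frames (training frames).
#' @param bin 0-based spatial bin per frame.
#' @param corridor corridor label per frame.
#' @param cfg a [decoder_config()].
#' @return a `decoder_model`: `P` (cells x states), `states` (data.frame bin,
#'   corridor), `T_jk`, `usable`.
#' @export
fit_decoder <- function(B, bin, corridor, cfg = decoder_config()) {
  corrs <- sort(unique(corridor))
  bins <- sort(unique(bin))
  states <- expand.grid(bin = bins, corridor = corrs,
                        stringsAsFactors = FALSE)
  st_of_frame <- match(paste(bin, corridor),
                       paste(states$bin, states$corridor))
  Tjk <- tabulate(st_of_frame, nrow(states))
  spike_frames <- rowsum(t(B), st_of_frame)     # present states x cells
  S <- matrix(0, nrow(states), ncol = nrow(B))
  S[as.integer(rownames(spike_frames)), ] <- spike_frames
  P <- t((S + cfg$pseudocount) / (Tjk + 2 * cfg$pseudocount))
  structure(list(P = P, states = states, T_jk = Tjk, usable = Tjk > 0,
                 pseudocount = cfg$pseudocount), class = "decoder_model")
}

# log-likelihood matrix (frames x states) for binary observations
decoder_loglik <- function(model, B) {
  logP <- log(model$P); log1P <- log1p(-model$P)
  t(B) %*% (logP - log1P) + matrix(colSums(log1P), ncol(B),
                                   nrow(model$states), byrow = TRUE)
}

#' Posterior over (position, corridor) for one frame
#'
#' Accumulates the Bernoulli log-likelihood over neurons with a uniform
#' prior over usable states, normalizes, and derives the marginals and the
#' point predictions: predicted position is the median of the position
#' marginal (smallest bin where the cumulative marginal reaches 0.5),
#' predicted corridor the argmax of the corridor marginal (ties go to the
#' first corridor).
#'
#' @param model a `decoder_model`.
#' @param svec binary spike vector (one frame).
#' @return list: `joint` (data.frame bin, corridor, posterior), `p_x`, `p_c`,
#'   `pred_bin`, `pred_corridor`.
#' @export
posterior <- function(model, svec) {
  if (!any(model$usable)) stop("no usable decoder states")
  ll <- decoder_loglik(model, matrix(svec, ncol = 1))[1, ]
  ll[!model$usable] <- -Inf
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  st <- model$states
  p_x <- tapply(post, st$bin, sum)
  p_c <- tapply(post, st$corridor, sum)
  bins <- as.integer(names(p_x))
  pred_bin <- bins[which(cumsum(p_x) >= 0.5)[1]]
  pred_corridor <- names(p_c)[which.max(p_c)]
  list(joint = data.frame(bin = st$bin, corridor = st$corridor,
                          posterior = post),
       p_x = p_x, p_c = p_c, pred_bin = pred_bin,
       pred_corridor = pred_corridor)
}

# vectorized predictions for a test set; returns per-frame predictions and
# the posterior mass on the true corridor
decode_frames <- function(model, B_test, true_bin, true_corridor) {
  ll <- decoder_loglik(model, B_test)
  ll[, !model$usable] <- -Inf
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  st <- model$states
  bins <- sort(unique(st$bin)); corrs <- sort(unique(st$corridor))
  Px <- vapply(bins, function(b) rowSums(post[, st$bin == b, drop = FALSE]),
               numeric(nrow(post)))
  Pc <- vapply(corrs, function(cc)
    rowSums(post[, st$corridor == cc, drop = FALSE]), numeric(nrow(post)))
  cum <- t(apply(Px, 1, cumsum))
  pred_bin <- bins[max.col(cum >= 0.5, ties.method = "first")]
  pred_cor <- corrs[max.col(Pc, ties.method = "first")]
  p_true_c <- Pc[cbind(seq_len(nrow(Pc)), match(true_corridor, corrs))]
  data.frame(true_bin = true_bin, true_corridor = true_corridor,
             pred_bin = pred_bin, pred_corridor = pred_cor,
             corridor_error = (pred_cor != true_corridor) * 1,
             soft_corridor_error = 1 - p_true_c,
             pos_error = abs(pred_bin - true_bin))
}

#' Cross-validated decoding of position and corridor identity
#'
#' Frames are split into `folds` contiguous blocks; each fold is decoded by
#' a model fitted on the remaining frames. Within each fold,
#' `n_subsamples` independent random subsamples of `min(n_neurons, N)`
#' neurons are decoded and the per-frame error indicators averaged (when all
#' neurons are used the subsamples are degenerate and the repeat count is
#' reduced to 1).
#'
#' @param s a `corridor_session`.
#' @param cfg a [decoder_config()].
#' @param seed RNG seed for fold-internal subsampling.
#' @return data.frame, one row per retained frame: true/predicted bin and
#'   corridor (from the first subsample), averaged `corridor_error`,
#'   `soft_corridor_error` and `pos_error`, plus `fold`.
#' @export
decode_cross_validated <- function(s, cfg = decoder_config(), seed = 1) {
  pp <- preprocess_for_decoding(s, cfg)
  N <- nrow(pp$B)
  if (N == 0) stop("no active neurons to decode from")
  set.seed(seed)
  nf <- ncol(pp$B)
  if (nf < cfg$folds) stop("fewer retained frames than folds")
  fold <- ceiling(seq_len(nf) / nf * cfg$folds)
  n_sub <- min(cfg$n_neurons, N)
  reps <- if (n_sub == N) 1L else cfg$n_subsamples
  res <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    test <- fold == f
    acc <- NULL
    for (r in seq_len(reps)) {
      cells <- if (n_sub == N) seq_len(N) else sample.int(N, n_sub)
      model <- fit_decoder(pp$B[cells, !test, drop = FALSE],
                           pp$bin[!test], pp$corridor[!test], cfg)
      d <- decode_frames(model, pp$B[cells, test, drop = FALSE],
                         pp$bin[test], pp$corridor[test])
      if (is.null(acc)) acc <- d
      else {
        acc$corridor_error <- acc$corridor_error + d$corridor_error
        acc$soft_corridor_error <- acc$soft_corridor_error +
          d$soft_corridor_error
        acc$pos_error <- acc$pos_error + d$pos_error
      }
    }
    acc$corridor_error <- acc$corridor_error / reps
    acc$soft_corridor_error <- acc$soft_corridor_error / reps
    acc$pos_error <- acc$pos_error / reps
    acc$fold <- f
    res[[f]] <- acc
  }
  out <- do.call(rbind, res)
  attr(out, "n_neurons_used") <- n_sub
  attr(out, "n_subsamples") <- reps
  out
}

#' Decoding error as a function of true position
#'
#' Mean corridor-identity error rate, posterior-mass (soft) corridor error
#' and absolute position error per true spatial bin, with frame counts.
#' Bins without test frames are absent (missing), never zero-filled.
#'
#' @param result output of [decode_cross_validated()].
#' @param by_corridor split curves per true corridor (default FALSE, pooled).
#' @return data.frame with per-bin error curves.
#' @export
error_by_position <- function(result, by_corridor = FALSE) {
  if (!nrow(result)) stop("empty decoding result")
  key <- if (by_corridor) interaction(result$true_bin, result$true_corridor,
                                      drop = TRUE)
         else factor(result$true_bin)
  agg <- lapply(split(result, key), function(d) data.frame(
    true_bin = d$true_bin[1],
    true_corridor = if (by_corridor) d$true_corridor[1] else NA,
    n_frames = nrow(d),
    corridor_error = mean(d$corridor_error),
    soft_corridor_error = mean(d$soft_corridor_error),
    mean_pos_error = mean(d$pos_error)))
  out <- do.call(rbind, c(agg, make.row.names = FALSE))
  out[order(out$true_bin), , drop = FALSE]
}
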