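# Pearson correlation that returns NA (not an error/warning) for
# zero-variance or insufficient input
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Population-vector correlation of two map sets
#'
#' `M[i, j] = corr(PV_i^A, PV_j^B)` where `PV_i` is the vector of all cells'
#' rates in spatial bin i. Requires identical cell sets and ordering in both
#' conditions. Zero-variance population vectors give `NA` entries, never
#' imputed values.
#'
#' @param mapsA,mapsB rate-map matrices, cells x bins.
#' @return list: `M` (bins x bins), `diagonal`.
#' @export
pv_correlation <- function(mapsA, mapsB) {
  if (!all(dim(mapsA) == dim(mapsB)))
    stop("map dimensions differ between conditions")
  if (nrow(mapsA) < 2) stop("need at least 2 cells")
  nb <- ncol(mapsA)
  M <- matrix(NA_real_, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb))
    M[i, j] <- safe_cor(mapsA[, i], mapsB[, j])
  list(M = M, diagonal = diag(M))
}

# lap-wise flattened activity vectors (cells x bins per lap) for one corridor
lap_activity_vectors <- function(s, corridor, v_min = 5, cells = NULL) {
  maps <- compute_rate_maps(s, v_min = v_min)
  mp <- maps[[corridor]]
  if (is.null(mp)) stop("no laps in corridor ", corridor)
  if (is.null(cells)) cells <- seq_len(n_cells(s))
  nl <- length(mp$lap_ids)
  av <- t(vapply(seq_len(nl), function(li)
    as.numeric(mp$lap_rate[cells, li, ]), numeric(length(cells) * s$n_bins)))
  list(av = av, lap_ids = mp$lap_ids, maps = maps)
}

#' Lap-to-lap correlation of population activity around an event
#'
#' `C[i, j] = corr(AV_i, AV_j)` with `AV_i` the flattened (all cells x all
#' bins) activity vector of lap i; computed per corridor over `window` laps
#' of that corridor before and after the event lap. `C_i` is the mean of row
#' i excluding the diagonal (missing entries skipped and counted).
#'
#' @param s a `corridor_session`.
#' @param event_lap 0-based session lap index of the event.
#' @param window laps of the corridor on each side (default 20).
#' @param v_min running-speed threshold (default 5).
#' @param cells optional cell subset.
#' @return named list per corridor: `C`, `C_i`, `lap_ids`, `is_post`,
#'   `n_missing` (NA pairs skipped in the row means).
#' @export
lap_to_lap_correlation <- function(s, event_lap, window = 20, v_min = 5,
                                   cells = NULL) {
  out <- list()
  for (cc in intersect(c("U", "R"), unique(s$corridor))) {
    lav <- lap_activity_vectors(s, cc, v_min = v_min, cells = cells)
    pre <- which(lav$lap_ids < event_lap)
    post <- which(lav$lap_ids >= event_lap)
    if (length(pre) < window || length(post) < window)
      stop("insufficient laps in corridor ", cc, ": ", length(pre),
           " before / ", length(post), " after the event, need ", window)
    sel <- c(tail(pre, window), head(post, window))
    av <- lav$av[sel, , drop = FALSE]
    n <- nrow(av)
    C <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      C[i, i] <- 1
      for (j in seq_len(n)) if (j > i)
        C[i, j] <- C[j, i] <- safe_cor(av[i, ], av[j, ])
    }
    offdiag <- C; diag(offdiag) <- NA
    out[[cc]] <- list(C = C, C_i = rowMeans(offdiag, na.rm = TRUE),
                      lap_ids = lav$lap_ids[sel],
                      is_post = lav$lap_ids[sel] >= event_lap,
                      n_missing = sum(is.na(offdiag)) / 2)
  }
  out
}

#' Lapwise correlation to a template population activity
#'
#' `B_i = corr(AV_i, TV)` where the template `TV` concatenates the tuning
#' curves of all cells estimated from the laps before (or after) the event,
#' excluding the `exclude` laps immediately around it. Lap correctness flags
#' are attached so post-event error laps can be compared with correct laps.
#'
#' @param s a `corridor_session`.
#' @param event_lap 0-based session lap of the event.
#' @param corridor corridor to analyze.
#' @param template `"pre"` or `"post"`.
#' @param exclude laps of the corridor excluded on each side of the event
#'   (default 20).
#' @param v_min running-speed threshold (default 5).
#' @param cells optional cell subset.
#' @return data.frame (lap, is_post, correct, B) plus attribute `template_laps`.
#' @export
template_correlation <- function(s, event_lap, corridor,
                                 template = c("pre", "post"), exclude = 20,
                                 v_min = 5, cells = NULL) {
  template <- match.arg(template)
  lav <- lap_activity_vectors(s, corridor, v_min = v_min, cells = cells)
  ids <- lav$lap_ids
  pre <- which(ids < event_lap); post <- which(ids >= event_lap)
  tpl_idx <- if (template == "pre") head(pre, max(0, length(pre) - exclude))
             else tail(post, max(0, length(post) - exclude))
  if (!length(tpl_idx)) stop("empty template lap set after exclusions")
  tpl_laps <- ids[tpl_idx]
  if (is.null(cells)) cells <- seq_len(n_cells(s))
  tmaps <- compute_rate_maps(s, v_min = v_min, laps = tpl_laps)
  tv <- as.numeric(tmaps[[corridor]]$lambda[cells, , drop = FALSE])
  B <- apply(lav$av, 1, function(v) safe_cor(v, tv))
  lt <- segment_laps(s)
  correct <- lt$correct[match(ids, lt$lap_index)]
  out <- data.frame(lap = ids, is_post = ids >= event_lap,
                    correct = correct, B = B)
  attr(out, "template_laps") <- tpl_laps
  out
}

#' Normalized activity difference between two conditions
#'
#' `(A - B)`, normalized separately for each cell by dividing its difference
#' row by the SD of that row across all positions. Rows with zero SD are
#' undefined (`NA`) and flagged.
#'
#' @param mapsA,mapsB rate-map matrices, cells x bins.
#' @return list: `diff` (cells x bins), `flagged` (logical per cell).
#' @export
normalized_activity_difference <- function(mapsA, mapsB) {
  if (!all(dim(mapsA) == dim(mapsB))) stop("map dimensions differ")
  d <- mapsA - mapsB
  sds <- apply(d, 1, function(v) sd(v[is.finite(v)]))
  flagged <- !is.finite(sds) | sds == 0
  out <- d / sds
  out[flagged, ] <- NA_real_
  list(diff = out, flagged = flagged)
}

#' Category-transition counts with a random-transition expectation
#'
#' Cross-tabulates co-registered cells' categories in a LOW- and a HIGH-
#' performance epoch. The expected count entering a target category from
#' source group g is `(size of g / total) * total entering the target`
#' (transitions distributed in proportion to source group sizes); the
#' chi-square statistic is `sum (O - E)^2 / E` with
#' `(rows - 1) * (cols - 1)` degrees of freedom.
#'
#' @param cat_low,cat_high character vectors of per-cell category labels for
#'   the same co-registered cells.
#' @return list: `observed`, `expected`, `chisq`, `df`, `p`.
#' @export
transition_table <- function(cat_low, cat_high) {
  if (!length(cat_low) || length(cat_low) != length(cat_high))
    stop("empty or mismatched cell sets")
  obs <- table(source = cat_low, target = cat_high)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  use <- expd > 0
  chisq <- sum((obs[use] - expd[use])^2 / expd[use])
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  p <- if (df >= 1) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(observed = obs, expected = expd, chisq = chisq, df = df, p = p)
}

#' Match ROIs across two epochs by trace correlation
#'
#' A pair of ROIs from two imaging epochs is considered the same cell iff
#' both their traces correlate above `r_thresh` with the corresponding
#' segments of a reference trace from the concatenated recording. Any ROI
#' participating in more than one surviving pair has all its pairs removed
#' (matches must be one-to-one).
#'
#' @param traces1 matrix (ROIs x frames) from epoch 1.
#' @param traces2 matrix (ROIs x frames) from epoch 2.
#' @param traces_concat matrix (reference ROIs x frames), columns covering
#'   epoch 1 then epoch 2.
#' @param r_thresh correlation threshold (default 0.958).
#' @return data.frame (roi1, roi2, ref, r1, r2, matched); matched pairs are
#'   one-to-one.
#' @export
match_rois <- function(traces1, traces2, traces_concat, r_thresh = 0.958) {
  n1 <- ncol(traces1); n2 <- ncol(traces2)
  if (ncol(traces_concat) != n1 + n2)
    stop("concatenated traces have ", ncol(traces_concat),
         " frames, expected ", n1 + n2)
  seg1 <- traces_concat[, seq_len(n1), drop = FALSE]
  seg2 <- traces_concat[, n1 + seq_len(n2), drop = FALSE]
  R1 <- suppressWarnings(cor(t(traces1), t(seg1)))
  R2 <- suppressWarnings(cor(t(traces2), t(seg2)))
  pairs <- list()
  for (k in seq_len(nrow(traces_concat))) {
    i <- which(R1[, k] > r_thresh)
    j <- which(R2[, k] > r_thresh)
    for (a in i) for (b in j)
      pairs[[length(pairs) + 1]] <- data.frame(
        roi1 = a, roi2 = b, ref = k, r1 = R1[a, k], r2 = R2[b, k])
  }
  if (!length(pairs))
    return(data.frame(roi1 = integer(0), roi2 = integer(0), ref = integer(0),
                      r1 = numeric(0), r2 = numeric(0), matched = logical(0)))
  tab <- unique(do.call(rbind, pairs)[, c("roi1", "roi2", "r1", "r2", "ref")])
  dup1 <- tab$roi1 %in% tab$roi1[duplicated(tab$roi1)]
  dup2 <- tab$roi2 %in% tab$roi2[duplicated(tab$roi2)]
  tab$matched <- !(dup1 | dup2)
  rownames(tab) <- NULL
  tab[, c("roi1", "roi2", "ref", "r1", "r2", "matched")]
}
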