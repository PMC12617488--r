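# 3-bin moving average over the bin dimension (columns); linear corridors,
# so edge bins average the existing neighbors only
smooth3_cols <- function(x) {
  nb <- ncol(x)
  if (nb < 3) return(x)
  out <- x
  out[, 2:(nb - 1)] <- (x[, 1:(nb - 2)] + x[, 2:(nb - 1)] + x[, 3:nb]) / 3
  out[, 1] <- (x[, 1] + x[, 2]) / 2
  out[, nb] <- (x[, nb - 1] + x[, nb]) / 2
  out
}

#' Per-corridor rate maps (tuning curves)
#'
#' Inferred spikes on running frames (speed strictly above `v_min`, gray
#' zones excluded) are assigned to 50 spatial bins, averaged across the
#' three neighboring bins, summed across laps, and divided by the occupancy
#' time per bin. Lap-wise binned rates (used for spatial reliability and
#' population analyses) receive the same 3-bin smoothing. Bins with zero
#' occupancy are `NA`.
#'
#' @param s a `corridor_session`.
#' @param v_min running-speed threshold, cm/s (default 5, strict `>`).
#' @param laps optional 0-based lap indices to restrict to.
#' @param parity `"all"`, `"odd"` or `"even"` lap parity subset (parity of
#'   the within-corridor lap order).
#' @param smooth apply the 3-bin moving average (default TRUE).
#' @param spikes optional replacement spike matrix (cells x frames).
#' @return named list per corridor: `lambda` (cells x bins, events/s),
#'   `occupancy` (seconds per bin), `lap_rate` (array cells x laps x bins),
#'   `lap_occ` (laps x bins), `lap_ids` (0-based session lap indices).
#' @export
compute_rate_maps <- function(s, v_min = 5, laps = NULL,
                              parity = c("all", "odd", "even"),
                              smooth = TRUE, spikes = NULL) {
  parity <- match.arg(parity)
  spk <- if (is.null(spikes)) s$spikes else spikes
  mask <- running_mask(s, v_min)
  if (!is.null(laps)) mask <- mask & s$lap %in% laps
  b1 <- rep(NA_integer_, n_frames(s))
  ng <- s$corridor != GRAY
  b1[ng] <- bin_position(s$position[ng], s$corridor_length, s$n_bins) + 1L
  dt <- 1 / s$frame_rate
  out <- list()
  for (cc in setdiff(unique(s$corridor), GRAY)) {
    idx <- which(mask & s$corridor == cc)
    if (!length(idx)) { out[[cc]] <- NULL; next }
    ulaps <- sort(unique(s$lap[idx]))
    if (parity != "all") {
      # within-corridor order: 1st, 3rd, ... are "odd" laps (1-based)
      want <- if (parity == "odd") seq_along(ulaps) %% 2 == 1
              else seq_along(ulaps) %% 2 == 0
      ulaps <- ulaps[want]
      idx <- idx[s$lap[idx] %in% ulaps]
      if (!length(idx)) { out[[cc]] <- NULL; next }
    }
    lap1 <- match(s$lap, ulaps)
    nl <- length(ulaps)
    bb <- b1[idx]; ll <- lap1[idx]
    occ <- tabulate(bb, s$n_bins) * dt
    tspk <- t(spk[, idx, drop = FALSE])
    cnt <- rowsum(tspk, bb)
    counts <- matrix(0, nrow(spk), s$n_bins)
    counts[, as.integer(rownames(cnt))] <- t(cnt)
    g <- (ll - 1L) * s$n_bins + bb
    lb <- rowsum(tspk, g)
    lap_counts_flat <- matrix(0, nrow(spk), nl * s$n_bins)
    lap_counts_flat[, as.integer(rownames(lb))] <- t(lb)
    lap_occ <- matrix(tabulate(g, nl * s$n_bins) * dt, nl, s$n_bins,
                      byrow = TRUE)
    lap_rate <- array(NA_real_, c(nrow(spk), nl, s$n_bins))
    for (li in seq_len(nl)) {
      cols <- (li - 1L) * s$n_bins + seq_len(s$n_bins)
      lc <- lap_counts_flat[, cols, drop = FALSE]
      if (smooth) lc <- smooth3_cols(lc)
      r <- sweep(lc, 2, lap_occ[li, ], "/")
      r[, lap_occ[li, ] == 0] <- NA_real_
      lap_rate[, li, ] <- r
    }
    if (smooth) counts <- smooth3_cols(counts)
    lambda <- sweep(counts, 2, occ, "/")
    lambda[, occ == 0] <- NA_real_
    out[[cc]] <- list(lambda = lambda, occupancy = occ, lap_rate = lap_rate,
                      lap_occ = lap_occ, lap_ids = ulaps)
  }
  out
}

#' Spatial reliability of a tuning curve
#'
#' Mean Pearson correlation between the cell's binned activity in individual
#' laps and its tuning curve. Laps with zero variance across bins are
#' skipped (their number is reported as an attribute); if every lap is
#' degenerate the value is `NA`.
#'
#' @param lap_rate matrix laps x bins of lap-wise binned rates.
#' @param lambda tuning curve over bins.
#' @return mean lap-tuning correlation, attribute `n_skipped`.
#' @export
spatial_reliability <- function(lap_rate, lambda) {
  rs <- apply(lap_rate, 1, function(v) {
    ok <- is.finite(v) & is.finite(lambda)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(lambda[ok]) == 0) return(NA_real_)
    cor(v[ok], lambda[ok])
  })
  out <- if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  attr(out, "n_skipped") <- sum(is.na(rs))
  out
}

#' Tuning specificity
#'
#' Corridor length divided by the width (SD) of the tuning curve, the SD
#' being the activity-weighted standard deviation of position. Activity in a
#' bin is treated as uniformly spread within the bin (adding w^2/12 to the
#' weighted variance), so a uniform curve gives exactly sqrt(12) and a
#' single-bin curve the finite maximum `n_bins * sqrt(12)`.
#'
#' @param lambda tuning curve over bins (`NA` allowed).
#' @param corridor_length cm.
#' @return specificity (dimensionless), `NA` when the curve is empty.
#' @export
tuning_specificity <- function(lambda, corridor_length = 106) {
  w <- corridor_length / length(lambda)
  lam <- ifelse(is.finite(lambda), lambda, 0)
  tot <- sum(lam)
  if (tot <= 0) return(NA_real_)
  ctr <- (seq_along(lambda) - 0.5) * w
  mu <- sum(lam * ctr) / tot
  v <- sum(lam * (ctr - mu)^2) / tot + w^2 / 12
  corridor_length / sqrt(v)
}

#' Skaggs spatial information of a tuning curve
#'
#' `sum_i p_i (lambda_i / lbar) log2(lambda_i / lbar)` in bits/event, with
#' `p_i` the occupancy share of bin i and `lbar` the occupancy-weighted mean
#' rate; zero-rate bins contribute 0. `per = "second"` multiplies by `lbar`.
#'
#' @param lambda tuning curve over bins.
#' @param occupancy seconds per bin.
#' @param per `"event"` (bits/event) or `"second"` (bits/s).
#' @return information content; `NA` when the mean rate is zero.
#' @export
spatial_information <- function(lambda, occupancy,
                                per = c("event", "second")) {
  per <- match.arg(per)
  ok <- occupancy > 0 & is.finite(lambda)
  p <- occupancy[ok] / sum(occupancy[ok])
  lam <- lambda[ok]
  lbar <- sum(p * lam)
  if (!isTRUE(lbar > 0)) return(NA_real_)
  r <- lam / lbar
  bits <- sum(ifelse(r > 0, p * r * log2(r), 0))
  if (per == "second") bits * lbar else bits
}

#' Corridor selectivity of the cells
#'
#' `(r_rew - r_unrew) / (r_rew + r_unrew)` where the two terms are the total
#' inferred spikes emitted in the R and U corridor (running frames only)
#' divided by the total time spent there; computed for the whole corridor
#' and within the four zones P1/P2/P3/RZ (the RZ window is
#' corridor-dependent: bins 42-45 in U, 45-48 in R).
#'
#' @param s a `corridor_session`.
#' @param v_min running-speed threshold (default 5).
#' @param laps optional 0-based lap restriction.
#' @param spikes optional replacement spike matrix.
#' @return data.frame: cell, whole, P1, P2, P3, RZ (each in `[-1, 1]` or
#'   `NA` when no time was spent in a zone).
#' @export
corridor_selectivity <- function(s, v_min = 5, laps = NULL, spikes = NULL) {
  spk <- if (is.null(spikes)) s$spikes else spikes
  mask <- running_mask(s, v_min)
  if (!is.null(laps)) mask <- mask & s$lap %in% laps
  b0 <- rep(NA_integer_, n_frames(s))
  ng <- s$corridor != GRAY
  b0[ng] <- bin_position(s$position[ng], s$corridor_length, s$n_bins)
  dt <- 1 / s$frame_rate
  zb <- zone_bins("neural")
  zones <- list(whole = NULL,
                P1 = list(U = zb$P1, R = zb$P1),
                P2 = list(U = zb$P2, R = zb$P2),
                P3 = list(U = zb$P3, R = zb$P3),
                RZ = list(U = zb$RZ_U, R = zb$RZ_R))
  res <- data.frame(cell = seq_len(nrow(spk)))
  for (zn in names(zones)) {
    rr <- list()
    for (cc in c("U", "R")) {
      m <- mask & s$corridor == cc
      if (!is.null(zones[[zn]])) m <- m & b0 %in% zones[[zn]][[cc]]
      tsec <- sum(m) * dt
      rr[[cc]] <- if (tsec > 0) rowSums(spk[, m, drop = FALSE]) / tsec
                  else rep(NA_real_, nrow(spk))
    }
    den <- rr$R + rr$U
    res[[zn]] <- ifelse(is.finite(den) & den > 0, (rr$R - rr$U) / den,
                        NA_real_)
  }
  res
}

#' Shuffle-null configuration
#'
#' Circular-shift surrogate generation: each shuffle shifts the cell's full
#' spike train relative to position by a uniform random offset of at least
#' `min_shift_s` seconds, divides the shifted train into `n_chunks`
#' contiguous chunks of at least `min_chunk_frames` frames, and randomly
#' permutes the chunk order; all tuning metrics are recomputed on the
#' surrogate. P-values are `(1 + #(null >= observed)) / (1 + n_shuffles)`.
#'
#' @param n_shuffles number of surrogates (default 1000).
#' @param n_chunks chunks to permute (default 5).
#' @param min_chunk_frames minimum chunk length (default 500).
#' @param min_shift_s minimum circular shift in seconds (default 10).
#' @param alpha family-wise significance level (default 0.05).
#' @return a `shuffle_config` list.
#' @export
shuffle_config <- function(n_shuffles = 1000, n_chunks = 5,
                           min_chunk_frames = 500, min_shift_s = 10,
                           alpha = 0.05) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  stopifnot(n_chunks >= 1, min_chunk_frames >= 1, alpha > 0, alpha < 1)
  structure(list(n_shuffles = n_shuffles, n_chunks = n_chunks,
                 min_chunk_frames = min_chunk_frames,
                 min_shift_s = min_shift_s, alpha = alpha),
            class = "shuffle_config")
}

# index matrix (frames x n_shuffles): circular shift then chunk permutation
shuffle_index_matrix <- function(n, cfg, frame_rate) {
  if (n < cfg$n_chunks * cfg$min_chunk_frames)
    stop("too few frames (", n, ") for ", cfg$n_chunks, " chunks of ",
         cfg$min_chunk_frames, " frames; lower n_chunks or min_chunk_frames")
  min_shift <- min(round(cfg$min_shift_s * frame_rate), floor(n / 4))
  extra <- n - cfg$n_chunks * cfg$min_chunk_frames
  S <- cfg$n_shuffles
  off <- sample(seq(min_shift, n - min_shift), S, replace = TRUE)
  base <- seq_len(n) - 1L
  out <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    idx0 <- ((base + off[j]) %% n) + 1L
    cuts <- sort(sample.int(extra + 1L, cfg$n_chunks - 1L,
                            replace = TRUE) - 1L)
    lens <- cfg$min_chunk_frames + diff(c(0L, cuts, extra))
    ends <- cumsum(lens); starts <- ends - lens + 1L
    ord <- sample.int(cfg$n_chunks)
    ro <- unlist(lapply(ord, function(k) starts[k]:ends[k]),
                 use.names = FALSE)
    out[, j] <- idx0[ro]
  }
  out
}

#' Cell-level tuning and selectivity significance by circular-shift shuffle
#'
#' For every cell, computes the observed spatial reliability, tuning
#' specificity and Skaggs information in both corridors plus the whole-
#' corridor and four zone selectivities, then builds the shuffle null
#' (circular shift + chunk permutation of the spike train, all metrics
#' recomputed with the same masks and binning) and derives one-sided
#' permutation p-values (high tail for the spatial metrics, high tail of
#' `|selectivity|` for the selectivity tests).
#'
#' @param s a `corridor_session`.
#' @param shuffle a [shuffle_config()].
#' @param v_min running-speed threshold (default 5).
#' @param laps optional 0-based lap restriction.
#' @param cells optional subset of cell indices (default all).
#' @return list: `metrics` (long data.frame cell x corridor with observed
#'   values and p-values), `selectivity` (per-cell observed values and
#'   p-values for whole/P1/P2/P3/RZ), `maps` (observed rate maps).
#' @export
tuning_significance <- function(s, shuffle = shuffle_config(), v_min = 5,
                                laps = NULL, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(s))
  maps <- compute_rate_maps(s, v_min = v_min, laps = laps)
  sel_obs <- corridor_selectivity(s, v_min = v_min, laps = laps)
  mask <- running_mask(s, v_min)
  if (!is.null(laps)) mask <- mask & s$lap %in% laps
  Tn <- n_frames(s)
  dt <- 1 / s$frame_rate
  ng <- s$corridor != GRAY
  b1 <- rep(NA_integer_, Tn)
  b1[ng] <- bin_position(s$position[ng], s$corridor_length, s$n_bins) + 1L
  nb <- s$n_bins
  zb <- zone_bins("neural")
  corrs <- intersect(c("U", "R"), names(maps))
  # fixed per-corridor frame structures
  cinfo <- lapply(corrs, function(cc) {
    idx <- which(mask & s$corridor == cc)
    ulaps <- maps[[cc]]$lap_ids
    l1 <- match(s$lap[idx], ulaps)
    keep <- !is.na(l1)
    idx <- idx[keep]; l1 <- l1[keep]
    bb <- b1[idx]
    zsel <- list(P1 = zb$P1, P2 = zb$P2, P3 = zb$P3,
                 RZ = if (cc == "U") zb$RZ_U else zb$RZ_R)
    zidx <- lapply(zsel, function(z) idx[(bb - 1L) %in% z])
    list(cc = cc, idx = idx, b = bb, lap1 = l1, nl = length(ulaps),
         occ = maps[[cc]]$occupancy, lap_occ = maps[[cc]]$lap_occ,
         tsec = length(idx) * dt,
         zidx = zidx, zsec = vapply(zidx, length, numeric(1)) * dt)
  })
  names(cinfo) <- corrs
  S <- shuffle$n_shuffles
  ctr <- (seq_len(nb) - 0.5) * (s$corridor_length / nb)
  w2_12 <- (s$corridor_length / nb)^2 / 12
  met_rows <- list(); sel_rows <- list()
  for (ci in cells) {
    spkv <- s$spikes[ci, ]
    FIDX <- shuffle_index_matrix(Tn, shuffle, s$frame_rate)
    SM <- matrix(spkv[FIDX], Tn, S)
    null_spatial <- list()
    zone_rate_null <- list(); whole_rate_null <- list()
    for (cc in corrs) {
      ni <- cinfo[[cc]]
      sm <- SM[ni$idx, , drop = FALSE]
      cnt <- rowsum(sm, ni$b)                       # present bins x S
      counts <- matrix(0, nb, S)
      counts[as.integer(rownames(cnt)), ] <- cnt
      counts_t <- t(smooth3_cols(t(counts)))        # smoothed, bins x S
      occ <- ni$occ
      lam <- counts_t / ifelse(occ > 0, occ, NA)
      # information (vectorized over shuffles)
      okb <- occ > 0
      p <- occ[okb] / sum(occ[okb])
      lbar <- colSums(p * lam[okb, , drop = FALSE])
      ratio <- sweep(lam[okb, , drop = FALSE], 2, lbar, "/")
      info_null <- colSums(p * ifelse(ratio > 0, ratio * log2(ratio), 0))
      # specificity
      lam0 <- ifelse(is.na(lam), 0, lam)
      tot <- colSums(lam0)
      mu <- colSums(lam0 * ctr) / tot
      vv <- colSums(lam0 * ctr^2) / tot - mu^2 + w2_12
      spec_null <- ifelse(tot > 0, s$corridor_length / sqrt(vv), NA)
      # reliability: lap x bin surrogate maps; masked-moment row correlations
      g <- (ni$lap1 - 1L) * nb + ni$b
      lbm <- rowsum(sm, g)
      rows_present <- as.integer(rownames(lbm))
      rel_null <- numeric(S)
      occm <- t(ni$lap_occ)                          # bins x laps
      validM <- (occm > 0) & okb                     # okb: total occ > 0
      m_l <- colSums(validM)
      for (j in seq_len(S)) {
        lapc <- matrix(0, nb, ni$nl)
        lapc[rows_present] <- lbm[, j]
        lapc <- t(smooth3_cols(t(lapc)))             # bins x laps, smoothed
        X <- lapc / occm
        X[!validM] <- 0
        l0 <- lam[, j]; l0[!okb] <- 0
        Sx <- colSums(X); Sxx <- colSums(X * X); Sxl <- colSums(X * l0)
        Sl <- colSums(validM * l0); Sll <- colSums(validM * l0^2)
        cv <- Sxl - Sx * Sl / m_l
        vx <- Sxx - Sx^2 / m_l
        vl <- Sll - Sl^2 / m_l
        ok <- m_l >= 3 & vx > 1e-12 & vl > 1e-12
        rel_null[j] <- if (any(ok))
          mean(cv[ok] / sqrt(vx[ok] * vl[ok])) else NA_real_
      }
      null_spatial[[cc]] <- list(info = info_null, spec = spec_null,
                                 rel = rel_null)
      whole_rate_null[[cc]] <- colSums(sm) / ni$tsec
      zone_rate_null[[cc]] <- lapply(names(ni$zidx), function(zn) {
        zi <- ni$zidx[[zn]]
        if (!length(zi) || ni$zsec[zn] == 0) rep(NA_real_, S)
        else colSums(SM[zi, , drop = FALSE]) / ni$zsec[zn]
      })
      names(zone_rate_null[[cc]]) <- names(ni$zidx)
    }
    # observed spatial metrics
    for (cc in corrs) {
      mp <- maps[[cc]]
      lam_obs <- mp$lambda[ci, ]
      rel_o <- as.numeric(spatial_reliability(mp$lap_rate[ci, , ], lam_obs))
      spec_o <- tuning_specificity(lam_obs, s$corridor_length)
      info_o <- spatial_information(lam_obs, mp$occupancy)
      nn <- null_spatial[[cc]]
      met_rows[[paste(ci, cc)]] <- data.frame(
        cell = ci, corridor = cc,
        reliability = rel_o, specificity = spec_o, information = info_o,
        p_reliability = perm_p(rel_o, nn$rel),
        p_specificity = perm_p(spec_o, nn$spec),
        p_information = perm_p(info_o, nn$info))
    }
    # selectivity p-values (|obs| vs |null|), needs both corridors
    sel_p <- rep(NA_real_, 5); names(sel_p) <- c("whole", "P1", "P2", "P3", "RZ")
    if (all(c("U", "R") %in% corrs)) {
      den <- whole_rate_null$R + whole_rate_null$U
      sel_null <- ifelse(den > 0, (whole_rate_null$R - whole_rate_null$U) / den,
                         NA)
      sel_p["whole"] <- perm_p(abs(sel_obs$whole[ci]), abs(sel_null))
      for (zn in c("P1", "P2", "P3", "RZ")) {
        den <- zone_rate_null$R[[zn]] + zone_rate_null$U[[zn]]
        zn_null <- ifelse(is.finite(den) & den > 0,
                          (zone_rate_null$R[[zn]] - zone_rate_null$U[[zn]]) / den,
                          NA)
        sel_p[zn] <- perm_p(abs(sel_obs[[zn]][ci]), abs(zn_null))
      }
    }
    sel_rows[[ci]] <- data.frame(
      cell = ci, whole = sel_obs$whole[ci], P1 = sel_obs$P1[ci],
      P2 = sel_obs$P2[ci], P3 = sel_obs$P3[ci], RZ = sel_obs$RZ[ci],
      p_whole = sel_p["whole"], p_P1 = sel_p["P1"], p_P2 = sel_p["P2"],
      p_P3 = sel_p["P3"], p_RZ = sel_p["RZ"], row.names = NULL)
  }
  list(metrics = do.call(rbind, c(met_rows, make.row.names = FALSE)),
       selectivity = do.call(rbind, c(sel_rows, make.row.names = FALSE)),
       maps = maps)
}

# permutation p-value, high tail; NA observed -> NA
perm_p <- function(obs, null) {
  if (!is.finite(obs)) return(NA_real_)
  null <- null[is.finite(null)]
  (1 + sum(null >= obs)) / (1 + length(null))
}

# mean Pearson correlation of lap rows with a tuning curve
mean_lap_cor <- function(lap_rate, lambda) {
  rs <- apply(lap_rate, 1, function(v) {
    ok <- is.finite(v) & is.finite(lambda)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(lambda[ok]) == 0) return(NA_real_)
    cor(v[ok], lambda[ok])
  })
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}

#' Classify cells from tuning and selectivity p-values
#'
#' Per cell, the Holm-Bonferroni step-down correction is applied across the
#' cell's own family of tests (3 spatial metrics x 2 corridors + 5
#' selectivity tests). A cell is spatially tuned in a corridor if any
#' corrected spatial test for that corridor is significant, and corridor-
#' selective if any corrected selectivity test is. Categories: `inactive`,
#' `active-untuned`, `spatial-only`, `selective-only`, `dual`.
#'
#' @param tun output of [tuning_significance()].
#' @param active logical per-cell activity flags (inactive cells keep their
#'   p-values but are labeled `inactive`).
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame: cell, tuned_U, tuned_R, spatially_tuned, selective,
#'   category.
#' @export
classify_cells <- function(tun, active = NULL, alpha = 0.05) {
  cells <- sort(unique(tun$metrics$cell))
  if (is.null(active)) active <- rep(TRUE, max(cells))
  out <- lapply(cells, function(ci) {
    m <- tun$metrics[tun$metrics$cell == ci, ]
    sl <- tun$selectivity[tun$selectivity$cell == ci, ]
    pv <- c(structure(c(m$p_reliability, m$p_specificity, m$p_information),
                      names = paste0(rep(c("rel_", "spec_", "info_"),
                                         each = nrow(m)), m$corridor)),
            whole = sl$p_whole, P1 = sl$p_P1, P2 = sl$p_P2, P3 = sl$p_P3,
            RZ = sl$p_RZ)
    if (anyNA(pv)) {
      known <- !is.na(pv)
      if (!any(known)) stop("cell ", ci, " has no p-values")
      pv <- pv[known]
    }
    adj <- stats::p.adjust(pv, method = "holm")
    sig <- adj <= alpha
    spat_names <- grep("^(rel|spec|info)_", names(pv))
    sel_names <- setdiff(seq_along(pv), spat_names)
    tuned_U <- any(sig[spat_names][grepl("U$", names(pv)[spat_names])])
    tuned_R <- any(sig[spat_names][grepl("R$", names(pv)[spat_names])])
    spatial <- tuned_U || tuned_R
    selective <- any(sig[sel_names])
    cat <- if (!active[ci]) "inactive"
      else if (spatial && selective) "dual"
      else if (spatial) "spatial-only"
      else if (selective) "selective-only"
      else "active-untuned"
    data.frame(cell = ci, tuned_U = tuned_U, tuned_R = tuned_R,
               spatially_tuned = spatial, selective = selective,
               category = cat)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Order cells by the location of peak activity
#'
#' Cells are sorted by the argmax bin of a reference rate map (conventionally
#' the odd laps of one corridor); ties keep cell-id order. The same ordering
#' can then be applied to other (cross-sorted) maps. Optionally each row is
#' normalized by its own peak for display.
#'
#' @param ref_maps reference rate-map matrix, cells x bins.
#' @param normalize divide each row by its peak (default FALSE).
#' @return list: `order` (cell indices), `peak_bin` (0-based per cell),
#'   `sorted` (reordered, optionally normalized reference map).
#' @export
sort_by_peak <- function(ref_maps, normalize = FALSE) {
  pk <- apply(ref_maps, 1, function(v) {
    v[!is.finite(v)] <- -Inf
    if (all(v == -Inf)) NA_integer_ else which.max(v)
  })
  ord <- order(pk, seq_len(nrow(ref_maps)), na.last = TRUE)
  m <- ref_maps[ord, , drop = FALSE]
  if (normalize) {
    mx <- apply(m, 1, max, na.rm = TRUE)
    m <- m / ifelse(mx > 0, mx, 1)
  }
  list(order = ord, peak_bin = pk - 1L, sorted = m)
}

#' Fraction of spatially tuned cells peaking at each position
#'
#' Each spatially tuned cell contributes its tuning-curve peak bin; the
#' profile is the count per bin divided by the number of active cells.
#'
#' @param tuned logical per-cell tuned flags for one corridor.
#' @param lambda rate-map matrix cells x bins for that corridor.
#' @param n_active denominator (number of active cells; default
#'   `length(tuned)`).
#' @return numeric vector, fraction per bin.
#' @export
tuned_fraction_by_position <- function(tuned, lambda,
                                       n_active = length(tuned)) {
  stopifnot(n_active >= 1)
  nb <- ncol(lambda)
  prof <- numeric(nb)
  for (ci in which(tuned)) {
    v <- lambda[ci, ]; v[!is.finite(v)] <- -Inf
    if (all(v == -Inf)) next
    k <- which.max(v)
    prof[k] <- prof[k] + 1
  }
  prof / n_active
}
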