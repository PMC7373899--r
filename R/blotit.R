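# Combined scaling-and-error model for replicate immunoblot quantifications.
#
# Signals are modeled log-normally: log y_igct = log s_g + log x_ct + eps,
# eps ~ N(0, sigma^2) with one sigma per target. With the reference gel's
# factor fixed at 1 this is a two-way linear model in the logs, so the
# generalized-least-squares estimates, their 1-sigma confidence intervals and
# the gel factors come straight from lm()'s coefficients and covariance.

#' Align replicate measurements across gels
#'
#' Merges replicate measurements of one target, taken on multiple gels with
#' unknown gel-specific multiplicative scaling factors, into one scaled
#' estimate with a 1-sigma confidence interval per (condition, time) cell.
#'
#' @param measurements data.frame with columns `target`, `gel`, `condition`,
#'   `time`, `signal` (signals strictly positive).
#' @param reference_rule function choosing the reference gel from the vector
#'   of gel ids of one target (default: the gel with the most measurements,
#'   mirroring the rule of scaling against the best-covered experiment).
#' @return object of class `ifndyn_scaled`: list with `estimates` (data.frame
#'   target, condition, time, estimate, sigma, n, unreliable) on the natural
#'   scale (geometric-mean type point estimates), `gel_factors` (data.frame
#'   target, gel, factor), `sigma_log` per target.
#' @export
align_replicates <- function(measurements,
                             reference_rule = function(gels) {
                               names(which.max(table(gels)))
                             }) {
  req <- c("target", "gel", "condition", "time", "signal")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "))
  if (any(measurements$signal <= 0))
    stop("signals must be strictly positive (log-normal model)")

  est_list <- list(); gf_list <- list(); sig <- c()
  for (tg in unique(measurements$target)) {
    d <- measurements[measurements$target == tg, ]
    d$cell <- interaction(d$condition, d$time, drop = TRUE)
    d$gel <- factor(d$gel)
    .check_connected(d, tg)
    ref <- reference_rule(as.character(d$gel))
    d$gel <- stats::relevel(d$gel, ref = ref)

    if (nlevels(d$gel) == 1L) {
      # single gel: no scaling freedom, estimates equal the measurements
      # (geometric mean over replicates within a cell)
      ag <- aggregate(log(signal) ~ cell + condition + time, data = d, mean)
      ns <- aggregate(signal ~ cell, data = d, length)
      sdl <- aggregate(log(signal) ~ cell, data = d,
                       function(x) if (length(x) > 1) sd(x) else NA_real_)
      est <- data.frame(target = tg, condition = ag$condition, time = ag$time,
                        estimate = exp(ag$`log(signal)`),
                        sigma_log = sdl$`log(signal)`[match(ag$cell, sdl$cell)] /
                          sqrt(ns$signal[match(ag$cell, ns$cell)]),
                        n = ns$signal[match(ag$cell, ns$cell)])
      gf <- data.frame(target = tg, gel = ref, factor = 1)
      sig[tg] <- NA_real_
    } else {
      fit <- lm(log(signal) ~ 0 + cell + gel, data = d)
      # vcov/summary emit a perfect-fit note on noiseless designs; the
      # zero-variance result is exactly what we want there
      cf <- coef(fit); V <- suppressWarnings(vcov(fit))
      cell_idx <- grep("^cell", names(cf))
      gel_idx <- grep("^gel", names(cf))
      cells <- sub("^cell", "", names(cf)[cell_idx])
      se <- sqrt(diag(V))[cell_idx]
      meta <- unique(d[, c("condition", "time")])
      meta$cell <- as.character(interaction(meta$condition, meta$time,
                                            drop = TRUE))
      m <- match(cells, meta$cell)
      ns <- table(as.character(d$cell))[cells]
      est <- data.frame(target = tg, condition = meta$condition[m],
                        time = meta$time[m],
                        estimate = exp(unname(cf[cell_idx])),
                        sigma_log = unname(se),
                        n = as.integer(ns))
      gf <- data.frame(target = tg,
                       gel = c(ref, sub("^gel", "", names(cf)[gel_idx])),
                       factor = c(1, exp(unname(cf[gel_idx]))))
      # noiseless designs trigger the perfect-fit note; the sigma is still 0
      sig[tg] <- suppressWarnings(summary(fit)$sigma)
    }
    est$unreliable <- is.na(est$sigma_log) | est$n < 2
    # 1-sigma CI half-width on the natural scale (delta method on log scale)
    est$sigma <- est$estimate * est$sigma_log
    est_list[[tg]] <- est
    gf_list[[tg]] <- gf
  }
  structure(list(estimates = do.call(rbind, est_list),
                 gel_factors = do.call(rbind, gf_list),
                 sigma_log = sig),
            class = "ifndyn_scaled")
}

# scaling graph connectivity: gels are linked when they share a (condition,
# time) cell; disconnected components cannot be scaled together
.check_connected <- function(d, target) {
  gels <- unique(as.character(d$gel))
  if (length(gels) <= 1) return(invisible(TRUE))
  comp <- setNames(seq_along(gels), gels)
  for (cl in split(as.character(d$gel), d$cell)) {
    ids <- unique(comp[cl])
    if (length(ids) > 1) comp[comp %in% ids] <- min(ids)
  }
  if (length(unique(comp)) > 1) {
    groups <- split(names(comp), comp)
    stop("disconnected scaling graph for target '", target, "': components ",
         paste(vapply(groups, paste, "", collapse = "+"), collapse = " | "))
  }
  invisible(TRUE)
}

#' Estimate molecules per cell from a spike-in calibration curve
#'
#' Fits a linear regression to the most linear contiguous region (>= 3 spike
#' levels, maximal R^2) of a recombinant-calibrator dilution series and
#' interpolates the endogenous signal, converting to molecules per cell.
#'
#' @param amounts calibrator amounts spiked into the lysate, in molecules
#'   (strictly increasing, >= 3 levels).
#' @param signals blot signals of the spiked lanes (same length).
#' @param endogenous_signal signal(s) of the unspiked endogenous sample;
#'   several replicate lysates may be given.
#' @param cells_per_lysate number of cells in the full lysate.
#' @param fraction_loaded fraction of the lysate loaded per lane (default 1).
#' @return list with `molecules_per_cell` (mean over samples), `sem`
#'   (standard error of the mean on the log-normal scale), `per_sample`,
#'   `fit` (the lm), `region` (indices of the linear region used).
#' @export
estimate_molecules_per_cell <- function(amounts, signals, endogenous_signal,
                                        cells_per_lysate,
                                        fraction_loaded = 1) {
  stopifnot(length(amounts) == length(signals), length(amounts) >= 3,
            all(diff(amounts) > 0), cells_per_lysate > 0,
            fraction_loaded > 0, fraction_loaded <= 1)
  # pick the contiguous subset (length >= 3) with the best linear fit
  cand <- NULL
  for (i in seq_len(length(amounts) - 2)) for (j in (i + 2):length(amounts)) {
    f <- lm(signals[i:j] ~ amounts[i:j])
    cand <- rbind(cand, data.frame(i = i, j = j,
                                   r2 = suppressWarnings(summary(f)$r.squared)))
  }
  # longest contiguous region whose R^2 is within half a percent of the best
  # (short noisy segments otherwise win spuriously)
  ok <- cand[cand$r2 >= 0.995 * max(cand$r2), ]
  ok <- ok[order(-(ok$j - ok$i), -ok$r2), ]
  best <- as.list(ok[1, ])
  idx <- best$i:best$j
  fit <- lm(s ~ a, data = data.frame(a = amounts[idx], s = signals[idx]))
  b <- coef(fit)
  lo <- min(signals[idx]); hi <- max(signals[idx])
  per <- vapply(endogenous_signal, function(y) {
    if (y < lo - 1e-9 || y > hi + 1e-9)
      stop("endogenous signal outside the fitted linear region; ",
           "extrapolation refused")
    (y - b[1]) / b[2]
  }, 0)
  mpc <- per / fraction_loaded / cells_per_lysate
  n <- length(mpc)
  sem <- if (n > 1) {
    # SEM on log-normal scale, reported on the natural scale
    m <- mean(log(mpc)); s <- sd(log(mpc)) / sqrt(n)
    exp(m) * s
  } else NA_real_
  list(molecules_per_cell = exp(mean(log(mpc))), sem = sem,
       per_sample = unname(mpc), fit = fit, region = idx)
}

#' Normalize qRT-PCR quantification cycles to reference genes
#'
#' Expression is computed as `E^(-Cq)` per record, normalized per sample to
#' the geometric mean of the three reference genes, and reported as fold
#' change over the baseline condition.
#'
#' @param records data.frame with columns `gene`, `condition`, `time`, `Cq`,
#'   `efficiency` (amplification efficiency in (1, 2]).
#' @param reference_genes character vector of reference genes (default
#'   GAPDH, HPRT, TBP); all must be present in every sample.
#' @param baseline_condition condition id of the baseline; fold changes are
#'   relative to the (gene-wise) baseline sample at `baseline_time`.
#' @param baseline_time time of the baseline sample (default 0).
#' @return data.frame gene, condition, time, normalized, fold_change.
#' @export
normalize_qpcr <- function(records,
                           reference_genes = c("GAPDH", "HPRT", "TBP"),
                           baseline_condition, baseline_time = 0) {
  req <- c("gene", "condition", "time", "Cq", "efficiency")
  stopifnot(all(req %in% names(records)))
  if (any(records$Cq <= 0 | records$Cq > 50))
    stop("Cq values must lie in (0, 50]")
  if (any(records$efficiency <= 1 | records$efficiency > 2))
    stop("amplification efficiencies must lie in (1, 2]")
  records$expr <- records$efficiency^(-records$Cq)
  records$sample <- interaction(records$condition, records$time, drop = TRUE)

  out <- list()
  for (s in levels(records$sample)) {
    d <- records[records$sample == s, ]
    refs <- d[d$gene %in% reference_genes, ]
    if (!all(reference_genes %in% refs$gene))
      stop("sample ", s, " rejected: missing reference gene(s) ",
           paste(setdiff(reference_genes, refs$gene), collapse = ", "))
    gm <- exp(mean(log(refs$expr[match(reference_genes, refs$gene)])))
    tgt <- d[!d$gene %in% reference_genes, ]
    if (nrow(tgt) == 0) next
    out[[s]] <- data.frame(gene = tgt$gene, condition = tgt$condition,
                           time = tgt$time, normalized = tgt$expr / gm)
  }
  res <- do.call(rbind, out)
  base <- res[res$condition == baseline_condition &
                res$time == baseline_time, ]
  if (nrow(base) == 0) stop("baseline sample not found")
  res$fold_change <- res$normalized /
    base$normalized[match(res$gene, base$gene)]
  rownames(res) <- NULL
  res
}

#' Borrow uncertainties for single-replicate datasets
#'
#' Primary-hepatocyte experiments carry no biological replicates; their
#' per-point uncertainty is estimated from the signal variance of a
#' high-dose-prestimulated time course under the assumption that this time
#' course is constant after stimulation, and assigned to every unreliable
#' (single-replicate) cell of the dataset.
#'
#' @param scaled an `ifndyn_scaled` from [align_replicates()].
#' @param reference_condition condition id whose (assumed constant)
#'   time course supplies the log-scale variance, per target.
#' @return the `ifndyn_scaled` with `sigma_log`/`sigma` filled in for
#'   unreliable cells and the flag cleared where a borrowed value exists.
#' @export
borrow_sigma <- function(scaled, reference_condition) {
  est <- scaled$estimates
  for (tg in unique(est$target)) {
    ref <- est[est$target == tg & est$condition == reference_condition, ]
    if (nrow(ref) < 2) next
    s <- sd(log(ref$estimate))   # scatter around the constant course
    sel <- est$target == tg & est$unreliable
    est$sigma_log[sel] <- s
    est$sigma[sel] <- est$estimate[sel] * s
    est$unreliable[sel] <- FALSE
  }
  scaled$estimates <- est
  scaled
}
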