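# Age associations of normalized MI and of phase-max proportions within PAC+
# cells, plus regional circular summaries of phase preference.

#' Standard 10-20 scalp regions
#'
#' Channel sets used for regional phase-preference analyses.
#'
#' @return Named list with `anterior` (Fp1, Fp2, F3, F4, F7, F8, Fz) and
#'   `posterior` (P3, P4, P7, P8, Pz, O1, O2) character vectors.
#' @export
pac_regions <- function() {
  list(
    anterior = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
    posterior = c("P3", "P4", "P7", "P8", "Pz", "O1", "O2")
  )
}

# Resolve a mask argument (logical vector over map cells, or a data frame of
# channel/lf_hz/hf_hz keys) into a logical vector aligned with `cells`.
resolve_mask <- function(cells, mask) {
  if (is.logical(mask)) {
    if (length(mask) != nrow(cells)) {
      stop("logical mask must have one entry per cell")
    }
    return(mask)
  }
  if (is.data.frame(mask)) {
    key <- paste(cells$channel, cells$lf_hz, cells$hf_hz)
    mkey <- paste(mask$channel, mask$lf_hz, mask$hf_hz)
    return(key %in% mkey)
  }
  stop("`mask` must be a logical vector or a data frame of cells")
}

#' Mean normalized MI over masked cells
#'
#' Arithmetic mean of `mi_norm` over the PAC+ cells of one recording's map;
#' this per-recording scalar feeds the age correlation.
#'
#' @param map A [pac_map()].
#' @param mask Logical vector over the map's cells, or a data frame with
#'   `channel`, `lf_hz`, `hf_hz` identifying the cells.
#'
#' @return Numeric scalar.
#' @export
mean_minorm_in_mask <- function(map, mask) {
  stopifnot(inherits(map, "pac_map"))
  m <- resolve_mask(map$cells, mask)
  if (!any(m)) stop("empty mask: no cells to average")
  mean(map$cells$mi_norm[m])
}

#' Pearson correlation of a per-recording statistic with age
#'
#' @param values Per-recording scalars (e.g. mean `mi_norm` in PAC+ cells).
#' @param ages Ages in months, aligned with `values`.
#'
#' @return List with `r`, `p` (two-sided) and `n`.
#' @export
pearson_age_correlation <- function(values, ages) {
  if (length(values) != length(ages)) stop("length mismatch")
  if (length(values) < 3L) stop("need at least 3 recordings")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(values, ages)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
}

#' Proportion of PAC+ cells with phase max in each bin
#'
#' For one recording, counts the masked (channel, frequency-pair) cells whose
#' phase max falls in each of the 18 phase bins and divides by the total
#' masked cell count, optionally restricted to a channel region.
#'
#' @param map A [pac_map()].
#' @param mask PAC+ mask (see [mean_minorm_in_mask()]).
#' @param region Optional character vector of channel labels to restrict to.
#'
#' @return Named numeric 18-vector summing to 1.
#' @export
phase_max_proportions <- function(map, mask, region = NULL) {
  stopifnot(inherits(map, "pac_map"))
  m <- resolve_mask(map$cells, mask)
  if (!is.null(region)) m <- m & map$cells$channel %in% region
  if (!any(m)) stop("no masked cells", if (!is.null(region)) " in region")
  pm <- map$cells$phase_max_deg[m]
  centers <- pac_bin_centers()
  counts <- tabulate(match(pm, centers), nbins = 18L)
  stats::setNames(counts / sum(counts), centers)
}

#' Per-bin age trends of phase-max proportions
#'
#' Correlates the per-recording proportion of PAC+ cells with phase max in
#' each of the 18 phase bins against age, flagging bins significant after
#' Bonferroni correction for the 18 tests (p < 0.05/18). Bins with constant
#' proportions across recordings are untestable and flagged.
#'
#' @param proportions Recordings-by-18 matrix of proportion vectors.
#' @param ages Ages in months, one per recording (>= 3 recordings).
#' @param alpha Family-wise level before Bonferroni division.
#'
#' @return An object of class `phase_trend`: a data frame with
#'   `bin_center_deg`, `r`, `p`, `significant`, `testable`.
#' @export
phase_trend <- function(proportions, ages, alpha = 0.05) {
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != 18L) stop("`proportions` must have 18 columns")
  if (nrow(proportions) != length(ages)) stop("length mismatch")
  if (nrow(proportions) < 3L) stop("need at least 3 recordings")
  out <- data.frame(
    bin_center_deg = pac_bin_centers(),
    r = NA_real_, p = NA_real_, significant = FALSE, testable = TRUE
  )
  for (b in seq_len(18L)) {
    v <- proportions[, b]
    if (stats::sd(v) == 0) {
      out$testable[b] <- FALSE
      next
    }
    ct <- stats::cor.test(v, ages)
    out$r[b] <- unname(ct$estimate)
    out$p[b] <- ct$p.value
    out$significant[b] <- ct$p.value < alpha / 18
  }
  class(out) <- c("phase_trend", "data.frame")
  out
}

#' Circular mean of phase values
#'
#' Argument of the mean unit vector of the given phases. Returned in degrees
#' in (-180, 180] so that the antipode of 0 is representable as 180; the
#' mean resultant length is attached as an attribute. An antipodal balance
#' (resultant length below 1e-9) has no defined mean and raises an error.
#'
#' @param phase_deg Numeric vector of phases in degrees (>= 1 value).
#'
#' @return Degrees, with attributes `resultant_length` and `n`.
#' @export
#' @examples
#' circular_mean_phase(c(170, -170))  # 180, not 0
circular_mean_phase <- function(phase_deg) {
  if (length(phase_deg) < 1L) stop("need at least one phase value")
  z <- mean(exp(1i * phase_deg * pi / 180))
  r <- Mod(z)
  if (r < 1e-9) stop("undefined circular mean: antipodal balance (resultant ~ 0)")
  out <- Arg(z) * 180 / pi
  attr(out, "resultant_length") <- r
  attr(out, "n") <- length(phase_deg)
  out
}

#' Group-level age trends within PAC+ cells
#'
#' Computes, from a clustering result: (i) the Pearson correlation between
#' age and each recording's mean `mi_norm` over PAC+ cells; (ii) overall and
#' per-region per-bin age trends of phase-max proportions (Bonferroni, 18
#' tests); (iii) per-region circular means of phase max pooled over PAC+
#' cells and recordings. Recordings with no PAC+ cell in a region are
#' excluded from that region's trend and listed in `excluded`.
#'
#' @param clusters A [pac_cluster()] result.
#' @param regions Named list of channel sets (default [pac_regions()]).
#'
#' @return An object of class `pac_trends` with elements `mi_age`
#'   (`r`, `p`, `n`), `mean_mi_norm` (per recording), `proportions`
#'   (per-region list of recordings-by-18 matrices), `trends` (per-region
#'   [phase_trend()] tables), `circular_means` (per-region degrees),
#'   `excluded`.
#' @export
pac_trends <- function(clusters, regions = pac_regions()) {
  stopifnot(inherits(clusters, "pac_clusters"))
  group <- clusters$group
  mask <- clusters$pac_plus
  if (!any(mask)) stop("no PAC+ cells: nothing to summarize")
  n_rec <- nrow(group$mi_norm)
  cells <- group$cells
  centers <- pac_bin_centers()

  mean_mi <- rowMeans(group$mi_norm[, mask, drop = FALSE])
  mi_age <- pearson_age_correlation(mean_mi, group$ages_months)

  scopes <- c(list(overall = unique(cells$channel)), regions)
  proportions <- list()
  trends <- list()
  circ <- list()
  excluded <- list()
  for (nm in names(scopes)) {
    in_scope <- mask & cells$channel %in% scopes[[nm]]
    if (!any(in_scope)) {
      excluded[[nm]] <- seq_len(n_rec)
      next
    }
    pm <- group$phase_max[, in_scope, drop = FALSE]
    props <- t(apply(pm, 1L, function(v) {
      tabulate(match(v, centers), nbins = 18L) / length(v)
    }))
    proportions[[nm]] <- props
    trends[[nm]] <- phase_trend(props, group$ages_months)
    # an antipodal balance (e.g. perfectly opposed regions pooled) has no
    # defined mean; record NA rather than abort
    circ[[nm]] <- tryCatch(
      circular_mean_phase(as.vector(pm)),
      error = function(e) {
        structure(NA_real_, resultant_length = NA_real_, n = length(pm))
      }
    )
    excluded[[nm]] <- integer(0)
  }
  structure(
    list(
      mi_age = mi_age, mean_mi_norm = mean_mi,
      proportions = proportions, trends = trends,
      circular_means = circ, excluded = excluded,
      ages_months = group$ages_months, regions = regions
    ),
    class = "pac_trends"
  )
}

#' @export
print.pac_trends <- function(x, ...) {
  cat(sprintf(
    "<pac_trends> MI_norm ~ age: r = %.4f, p = %.3g (n = %d)\n",
    x$mi_age$r, x$mi_age$p, x$mi_age$n
  ))
  for (nm in names(x$circular_means)) {
    cm <- x$circular_means[[nm]]
    nsig <- sum(x$trends[[nm]]$significant, na.rm = TRUE)
    if (is.na(cm)) {
      cat(sprintf("  %s: circular mean phase max undefined (antipodal); %d significant trend bin(s)\n",
                  nm, nsig))
    } else {
      cat(sprintf(
        "  %s: circular mean phase max %.1f deg (R = %.2f); %d significant trend bin(s)\n",
        nm, as.numeric(cm), attr(cm, "resultant_length"), nsig
      ))
    }
  }
  invisible(x)
}

#' Median MI_norm by age plot
#'
#' Plots the median per-recording mean `mi_norm` in PAC+ cells against age
#' with an interquartile band (the summary used in developmental displays;
#' the correlation itself is computed on the means).
#'
#' @param x A `pac_trends` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pac_trends <- function(x, ...) {
  ages <- sort(unique(x$ages_months))
  med <- vapply(ages, function(a)
    stats::median(x$mean_mi_norm[x$ages_months == a]), numeric(1))
  q1 <- vapply(ages, function(a)
    stats::quantile(x$mean_mi_norm[x$ages_months == a], 0.25), numeric(1))
  q3 <- vapply(ages, function(a)
    stats::quantile(x$mean_mi_norm[x$ages_months == a], 0.75), numeric(1))
  graphics::plot(ages, med, type = "b", pch = 16,
                 ylim = range(c(q1, q3)),
                 xlab = "Age (months)", ylab = "Median MI_norm in PAC+ cells",
                 ...)
  graphics::polygon(c(ages, rev(ages)), c(q1, rev(q3)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(ages, med, type = "b", pch = 16)
  invisible(x)
}
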