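# Cluster-based identification of significant PAC (PAC+): per-channel t-maps
# of MI_raw against the surrogate mean, 4-connected clustering over the
# frequency-pair grid, and a flip-half permutation null for cluster masses.

#' Assemble a group dataset from per-recording PAC maps
#'
#' Stacks the PAC maps of all usable recordings into aligned
#' recordings-by-cells matrices; all maps must share the same channels and
#' valid-pair grid.
#'
#' @param maps List of [pac_map()] objects.
#' @param ages_months Optional ages; defaults to each map's metadata.
#'
#' @return An object of class `pac_group`: `cells` (data frame of `channel`,
#'   `lf_hz`, `hf_hz` and grid indices), matrices `mi_raw`, `surr_mean`,
#'   `mi_norm`, `phase_max` (recordings x cells), `ages_months`,
#'   `subject_ids` and the shared `spec`.
#' @export
pac_group <- function(maps, ages_months = NULL) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "pac_map")))
  key <- function(m) paste(m$cells$channel, m$cells$lf_hz, m$cells$hf_hz)
  k0 <- key(maps[[1L]])
  for (m in maps[-1L]) {
    if (!identical(key(m), k0)) {
      stop("all PAC maps must share the same channels and valid-pair grid")
    }
  }
  spec <- maps[[1L]]$spec
  cells <- maps[[1L]]$cells[, c("channel", "lf_hz", "hf_hz")]
  cells$lf_idx <- match(cells$lf_hz, spec$lf_centers)
  cells$hf_idx <- match(cells$hf_hz, spec$hf_centers)
  grab <- function(col) t(vapply(maps, function(m) m$cells[[col]],
                                 numeric(nrow(cells))))
  ages <- ages_months %||% vapply(maps, function(m) m$age_months, numeric(1))
  structure(
    list(
      cells = cells,
      mi_raw = grab("mi_raw"), surr_mean = grab("surr_mean"),
      mi_norm = grab("mi_norm"), phase_max = grab("phase_max_deg"),
      ages_months = ages,
      subject_ids = vapply(maps, function(m) as.character(m$subject_id),
                           character(1)),
      spec = spec
    ),
    class = "pac_group"
  )
}

#' @export
print.pac_group <- function(x, ...) {
  cat(sprintf("<pac_group> %d recording(s) x %d cells (%d channel(s))\n",
              nrow(x$mi_raw), nrow(x$cells),
              length(unique(x$cells$channel))))
  invisible(x)
}

# t statistics of paired differences (rows = recordings): returns t, p and a
# zero-variance flag per column.
paired_t_cols <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  s <- sqrt(v)
  zero <- s <= .Machine$double.eps^0.5 * pmax(abs(m), 1)
  t <- ifelse(zero, NA_real_, m / (s / sqrt(n)))
  p <- ifelse(zero, NA_real_, 2 * stats::pt(-abs(t), df = n - 1))
  list(t = t, p = p, zero_var = zero, df = n - 1)
}

#' Per-cell t-map of MI_raw against the surrogate mean
#'
#' At every (channel, frequency-pair) cell, a paired two-sided t test
#' compares the recordings' raw modulation indices with their surrogate means
#' — the surrogate mean plays the role of a control condition that preserves
#' the signal's spectral characteristics but not its coupling. Cells with
#' zero variance of the paired differences are flagged and excluded from
#' masking.
#'
#' @param group A [pac_group()] with at least 3 recordings.
#'
#' @return List with `t`, `p` (vectors aligned with `group$cells`),
#'   `zero_var`, `df`.
#' @export
pac_t_map <- function(group) {
  stopifnot(inherits(group, "pac_group"))
  if (nrow(group$mi_raw) < 3L) stop("need at least 3 recordings")
  paired_t_cols(group$mi_raw - group$surr_mean)
}

#' Threshold a t-map into a significance mask
#'
#' @param tmap A [pac_t_map()] result.
#' @param alpha Two-sided significance level (strict `p < alpha`).
#'
#' @return Logical vector; `FALSE` for zero-variance cells.
#' @export
threshold_mask <- function(tmap, alpha = 0.05) {
  !is.na(tmap$p) & tmap$p < alpha
}

#' Label 4-connected clusters on a frequency-pair grid
#'
#' Connected-component labelling of a logical low-frequency by high-frequency
#' mask under 4-connectivity (adjacent LF step or adjacent HF step; no
#' diagonals). `NA` entries (frequency pairs excluded from analysis) are
#' treated as background and never bridge two clusters.
#'
#' @param mask Logical matrix (LF x HF), `NA` allowed.
#'
#' @return Integer matrix of the same shape: 0 for background, 1..k for
#'   clusters.
#' @export
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1:2] <- TRUE; m[3, 3] <- TRUE
#' label_clusters(m)
label_clusters <- function(mask) {
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  for (j0 in seq_len(nc)) {
    for (i0 in seq_len(nr)) {
      if (!mask[i0, j0] || labels[i0, j0] > 0L) next
      lab <- lab + 1L
      # preallocated stack of linear indices
      stack <- integer(nr * nc)
      stack[1L] <- (j0 - 1L) * nr + i0
      top <- 1L
      labels[i0, j0] <- lab
      while (top > 0L) {
        lin <- stack[top]; top <- top - 1L
        i <- ((lin - 1L) %% nr) + 1L
        j <- ((lin - 1L) %/% nr) + 1L
        for (d in c(-1L, 1L, -nr, nr)) {
          if (d == -1L && i == 1L) next
          if (d == 1L && i == nr) next
          if (d == -nr && j == 1L) next
          if (d == nr && j == nc) next
          nb <- lin + d
          if (mask[nb] && labels[nb] == 0L) {
            labels[nb] <- lab
            top <- top + 1L
            stack[top] <- nb
          }
        }
      }
    }
  }
  labels
}

#' Cluster-level statistics (masses)
#'
#' The mass of a cluster is the sum over its cells of `t - t_crit`, where
#' `t_crit` is the minimum t value needed to reach the two-sided significance
#' level at the group's degrees of freedom; subtracting it first makes masses
#' positive by construction for supra-threshold cells.
#'
#' @param t_values Numeric vector/matrix of t statistics.
#' @param labels Integer labels of the same shape (0 = background).
#' @param t_crit Critical t value, e.g. `qt(1 - alpha/2, df)`.
#'
#' @return Named numeric vector of masses, one per cluster label.
#' @export
cluster_masses <- function(t_values, labels, t_crit) {
  keep <- labels > 0L
  if (!any(keep)) return(numeric(0))
  out <- tapply(abs(t_values[keep]) - t_crit, labels[keep], sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Flip MI_raw and the surrogate mean for a random half of recordings
#'
#' The permutation step of the null construction: for `floor(N/2)` randomly
#' chosen recordings, `mi_raw` and `surr_mean` are swapped at every cell;
#' under the null hypothesis of no coupling the two are exchangeable.
#' Applying the same flip selection twice restores the original dataset.
#'
#' @param group A [pac_group()].
#' @param seed Optional seed for the selection.
#'
#' @return A `pac_group` with a `flipped` attribute (the flipped row
#'   indices).
#' @export
flip_half <- function(group, seed = NULL) {
  stopifnot(inherits(group, "pac_group"))
  n <- nrow(group$mi_raw)
  if (n < 2L) stop("need at least 2 recordings to flip")
  pick <- with_seed(seed, sort(sample.int(n, n %/% 2L)))
  tmp <- group$mi_raw[pick, , drop = FALSE]
  group$mi_raw[pick, ] <- group$surr_mean[pick, , drop = FALSE]
  group$surr_mean[pick, ] <- tmp
  attr(group, "flipped") <- pick
  group
}

# Observed clustering at one alpha: mask -> per-channel labels -> masses.
# Returns per-cell labels (channel-unique), and a cluster table.
cluster_once <- function(group, t, p, alpha, t_crit) {
  cells <- group$cells
  sig <- !is.na(p) & p < alpha
  labels_vec <- integer(nrow(cells))
  cl_rows <- list()
  offset <- 0L
  for (ch in unique(cells$channel)) {
    in_ch <- which(cells$channel == ch)
    grid <- matrix(NA, length(group$spec$lf_centers),
                   length(group$spec$hf_centers))
    grid[cbind(cells$lf_idx[in_ch], cells$hf_idx[in_ch])] <- sig[in_ch]
    lab <- label_clusters(grid)
    lv <- lab[cbind(cells$lf_idx[in_ch], cells$hf_idx[in_ch])]
    tgrid <- matrix(NA_real_, nrow(grid), ncol(grid))
    tgrid[cbind(cells$lf_idx[in_ch], cells$hf_idx[in_ch])] <- t[in_ch]
    if (max(lab) > 0L) {
      mass <- cluster_masses(tgrid[lab > 0L & !is.na(tgrid)],
                             lab[lab > 0L & !is.na(tgrid)], t_crit)
      for (id in seq_len(max(lab))) {
        cl_rows[[length(cl_rows) + 1L]] <- data.frame(
          channel = ch, cluster_id = offset + id,
          n_cells = sum(lv == id, na.rm = TRUE),
          mass = as.numeric(mass[as.character(id)]),
          stringsAsFactors = FALSE
        )
      }
    }
    labels_vec[in_ch] <- ifelse(is.na(lv) | lv == 0L, 0L,
                                offset + lv)
    offset <- offset + max(lab)
  }
  clusters <- if (length(cl_rows)) do.call(rbind, cl_rows) else
    data.frame(channel = character(0), cluster_id = integer(0),
               n_cells = integer(0), mass = numeric(0))
  list(labels = labels_vec, clusters = clusters)
}

#' Permutation null distribution of cluster masses
#'
#' Repeats the flip-half / t-map / threshold / label / mass pipeline
#' `n_perm` times (default 200). With `null_mode = "pooled"` (default) the
#' null collects every cluster mass from every permutation and channel — the
#' literal "distribution of cluster sizes"; with `null_mode = "max"` it
#' collects the per-permutation maximum mass, the standard family-wise
#' construction. A permutation yielding no supra-threshold cells contributes
#' a mass of 0.
#'
#' @param group A [pac_group()].
#' @param alpha Cell-level threshold.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param null_mode `"pooled"` or `"max"`.
#'
#' @return List with `masses` (the null distribution per `null_mode`),
#'   `per_perm_max`, `n_perm`, `null_mode`, `alpha`.
#' @export
permutation_null <- function(group, alpha = 0.05, n_perm = 200, seed = NULL,
                             null_mode = c("pooled", "max")) {
  null_mode <- match.arg(null_mode)
  stopifnot(inherits(group, "pac_group"))
  d <- group$mi_raw - group$surr_mean
  n <- nrow(d)
  t_crit <- stats::qt(1 - alpha / 2, df = n - 1)
  with_seed(seed, {
    pooled <- list()
    per_max <- numeric(n_perm)
    for (perm in seq_len(n_perm)) {
      pick <- sample.int(n, n %/% 2L)
      d2 <- d
      d2[pick, ] <- -d2[pick, , drop = FALSE]   # swap mi_raw <-> surr_mean
      tp <- paired_t_cols(d2)
      res <- cluster_once(group, tp$t, tp$p, alpha, t_crit)
      masses <- res$clusters$mass
      if (length(masses) == 0L) masses <- 0
      pooled[[perm]] <- masses
      per_max[perm] <- max(masses)
    }
    all_masses <- unlist(pooled)
    list(
      masses = if (null_mode == "pooled") all_masses else per_max,
      per_perm_max = per_max,
      n_perm = n_perm, null_mode = null_mode, alpha = alpha
    )
  })
}

#' PAC+ mask from observed clusters and a permutation null
#'
#' Observed clusters whose mass reaches the 95th percentile of the null
#' distribution are retained; all their cells are marked PAC+. Clusters below
#' the percentile are removed from further analysis.
#'
#' @param clusters Observed cluster table (from the clustering step).
#' @param labels Per-cell cluster labels aligned with the group's cells.
#' @param null A [permutation_null()] result.
#' @param percentile Retention percentile (default 0.95).
#'
#' @return List with `mask` (logical per cell), `clusters` (table with
#'   `null_percentile` and `significant` columns), `threshold`.
#' @export
pac_positive_mask <- function(clusters, labels, null, percentile = 0.95) {
  if (nrow(clusters) > 0L && length(null$masses) == 0L) {
    stop("empty null distribution with nonempty observed clusters")
  }
  thr <- if (length(null$masses)) {
    as.numeric(stats::quantile(null$masses, percentile))
  } else {
    Inf
  }
  ecdf_null <- if (length(null$masses)) stats::ecdf(null$masses) else NULL
  clusters$null_percentile <- if (nrow(clusters) && !is.null(ecdf_null)) {
    ecdf_null(clusters$mass)
  } else {
    numeric(0)
  }
  clusters$significant <- nrow(clusters) > 0 & clusters$mass >= thr
  keep_ids <- clusters$cluster_id[clusters$significant]
  list(mask = labels %in% keep_ids, clusters = clusters, threshold = thr)
}

#' Identify PAC+ clusters across recordings
#'
#' The group-level orchestrator: paired t-map of `mi_raw` vs `surr_mean`,
#' strict `p < alpha` masking, per-channel 4-connected clustering, cluster
#' masses (sum of `t - t_crit`), a flip-half permutation null, and retention
#' of observed clusters at the null's 95th percentile.
#'
#' @param x A list of [pac_map()] objects or a [pac_group()].
#' @param alpha Cell-level two-sided significance level.
#' @param n_perm Number of flip-half permutations.
#' @param null_mode `"pooled"` (default) or `"max"`; see
#'   [permutation_null()].
#' @param percentile Cluster retention percentile.
#' @param seed Optional seed.
#'
#' @return An object of class `pac_clusters`: the `group`, `t`/`p` vectors,
#'   `t_crit`, per-cell `labels` and `pac_plus` mask, the `clusters` table
#'   (channel, cluster_id, n_cells, mass, null_percentile, significant), the
#'   `null`, and `fraction_selected` — the fraction of (channel x valid pair)
#'   cells marked PAC+.
#' @export
pac_cluster <- function(x, alpha = 0.05, n_perm = 200,
                        null_mode = c("pooled", "max"), percentile = 0.95,
                        seed = NULL) {
  null_mode <- match.arg(null_mode)
  group <- if (inherits(x, "pac_group")) x else pac_group(x)
  tp <- pac_t_map(group)
  t_crit <- stats::qt(1 - alpha / 2, df = tp$df)
  obs <- cluster_once(group, tp$t, tp$p, alpha, t_crit)
  null <- permutation_null(group, alpha = alpha, n_perm = n_perm,
                           seed = seed, null_mode = null_mode)
  pos <- pac_positive_mask(obs$clusters, obs$labels, null)
  structure(
    list(
      group = group, t = tp$t, p = tp$p, zero_var = tp$zero_var,
      t_crit = t_crit, labels = obs$labels,
      clusters = pos$clusters, null = null,
      pac_plus = pos$mask, threshold = pos$threshold,
      fraction_selected = mean(pos$mask),
      alpha = alpha, n_perm = n_perm, null_mode = null_mode
    ),
    class = "pac_clusters"
  )
}

#' @export
print.pac_clusters <- function(x, ...) {
  cat(sprintf(
    "<pac_clusters> %d recording(s), %d cells: %d cluster(s), %d significant; %.1f%% of cells PAC+\n",
    nrow(x$group$mi_raw), length(x$pac_plus), nrow(x$clusters),
    sum(x$clusters$significant), 100 * x$fraction_selected
  ))
  cat(sprintf("  null: %s over %d permutations, mass threshold %.3f\n",
              x$null_mode, x$n_perm, x$threshold))
  invisible(x)
}

#' @export
summary.pac_clusters <- function(object, ...) {
  print(object)
  if (nrow(object$clusters)) {
    print(object$clusters, row.names = FALSE)
  }
  invisible(object$clusters)
}
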