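ANALYSIS_SCOPES <- c("whole_brain", "L", "R")
GROUP_PAIRINGS <- list(c("LGG", "HC"), c("HGG", "HC"), c("LGG", "HGG"))

#' Per-subject network means for the three analysis scopes
#'
#' For one subject's binary graph, computes nodal metrics on the
#' whole-brain graph and on the left- and right-hemisphere induced
#' subgraphs (metrics are recomputed on each subgraph, not averaged
#' from whole-brain values), then averages each metric over the nodes
#' in scope.
#'
#' @param graph `binary_graph` over all ROIs of `parc`.
#' @param parc parcellation table.
#' @return data.frame with one row per scope (`whole_brain`, `L`, `R`)
#'   and the seven metric means.
#' @export
subject_scope_means <- function(graph, parc) {
  validate_parcellation(parc)
  rows <- lapply(ANALYSIS_SCOPES, function(sc) {
    g <- if (sc == "whole_brain") graph
         else graph_subgraph(graph, parc$roi_id[parc$hemisphere == sc])
    network_summary(nodal_metrics(g), scope_label = sc)
  })
  do.call(rbind, rows)
}

#' Scope means for every subject of a cohort
#'
#' @param graphs named list of `binary_graph`s (names = subject ids).
#' @param parc parcellation table.
#' @return data.frame: `subject_id`, `scope`, `n_nodes`, seven metric
#'   columns.
#' @export
cohort_scope_means <- function(graphs, parc) {
  out <- lapply(names(graphs), function(sid) {
    cbind(subject_id = sid, subject_scope_means(graphs[[sid]], parc))
  })
  do.call(rbind, out)
}

#' @noRd
comparison_row <- function(scope, node, metric, group_a, group_b, cmp) {
  data.frame(scope = scope, node = node, metric = metric,
             group_a = group_a, group_b = group_b,
             test_used = cmp$test_used, statistic = cmp$statistic,
             p_raw = cmp$p, p_fdr = NA_real_,
             direction = cmp$direction,
             n_a = cmp$n_a, n_b = cmp$n_b,
             jb_p_a = cmp$jb_p_a, jb_p_b = cmp$jb_p_b,
             stringsAsFactors = FALSE)
}

#' Whole-brain and hemispheric group analysis
#'
#' The first-level group design: for each scope (whole-brain, left
#' hemisphere, right hemisphere) and each of the seven network-mean
#' metrics, compares LGG vs HC, HGG vs HC and LGG vs HGG with the
#' normality-gated test of [compare_groups()]; additionally contrasts
#' the left vs right hemispheric network within each group (paired per
#' subject by default).  Benjamini-Hochberg adjustment is applied
#' within each (scope, pairing) family across the seven metrics.
#'
#' @param scope_means data.frame from [cohort_scope_means()].
#' @param manifest cohort manifest ([cohort_manifest()]).
#' @param alpha_normality Jarque-Bera gate level.
#' @param paired_lr compare L vs R as paired per-subject observations
#'   (default) or as independent samples.
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return data.frame of group comparisons (one row per scope x
#'   pairing x metric) with columns `scope`, `node` (always
#'   `"network-mean"`), `metric`, `group_a`, `group_b`, `test_used`,
#'   `statistic`, `p_raw`, `p_fdr`, `direction`, sample sizes and gate
#'   records.
#' @export
hemispheric_analysis <- function(scope_means, manifest,
                                 alpha_normality = 0.05,
                                 paired_lr = TRUE, welch = FALSE) {
  groups_present <- unique(manifest$group)
  if (length(groups_present) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sm <- merge(scope_means, manifest[, c("subject_id", "group")],
              by = "subject_id")
  rows <- list()

  pick <- function(scope, group, metric) {
    v <- sm[sm$scope == scope & sm$group == group, ]
    v <- v[order(v$subject_id), ]
    v[[metric]]
  }

  for (sc in ANALYSIS_SCOPES) {
    for (pr in GROUP_PAIRINGS) {
      if (!all(pr %in% groups_present)) {
        gc_log("skipping %s vs %s in scope %s: group missing",
               pr[1], pr[2], sc)
        next
      }
      for (m in METRIC_NAMES) {
        cmp <- compare_groups(pick(sc, pr[1], m), pick(sc, pr[2], m),
                              alpha_normality = alpha_normality,
                              welch = welch)
        rows[[length(rows) + 1L]] <-
          comparison_row(sc, "network-mean", m, pr[1], pr[2], cmp)
      }
    }
  }
  # paired left-vs-right contrast within each group
  for (g in intersect(c("HC", "LGG", "HGG"), groups_present)) {
    for (m in METRIC_NAMES) {
      cmp <- compare_groups(pick("L", g, m), pick("R", g, m),
                            alpha_normality = alpha_normality,
                            paired = paired_lr, welch = welch)
      rows[[length(rows) + 1L]] <-
        comparison_row("L_vs_R", "network-mean", m, g, g, cmp)
    }
  }
  out <- do.call(rbind, rows)
  fam <- interaction(out$scope, out$group_a, out$group_b, drop = TRUE)
  out$p_fdr <- stats::ave(out$p_raw, fam, FUN = fdr_correct)
  out
}

#' Lobar (tumor-location) nodal analysis
#'
#' For every lobe that hosts at least one patient's tumor, restricts
#' the patient groups to subjects with that tumor location and compares
#' each node of that lobe (both hemispheres, as evaluated in the
#' whole-brain network) between groups, metric by metric.  HC subjects
#' are always included in full.  Comparisons with fewer than `min_n`
#' subjects on either side are skipped with a log entry.
#' Benjamini-Hochberg adjustment is applied across nodes within each
#' (lobe, metric, pairing) family.
#'
#' @param nodal list of per-subject nodal metric tables (from
#'   [nodal_metrics()] on the whole-brain graph), named by subject id.
#' @param manifest cohort manifest.
#' @param parc parcellation table.
#' @param alpha_normality Jarque-Bera gate level.
#' @param min_n minimum subjects per side (default 3).
#' @param welch use Welch t-tests.
#' @return data.frame with columns `lobe`, `node`, `node_name`,
#'   `metric`, `group_a`, `group_b`, `test_used`, `statistic`,
#'   `p_raw`, `p_fdr`, `direction`, `n_a`, `n_b`.
#' @export
lobar_analysis <- function(nodal, manifest, parc,
                           alpha_normality = 0.05, min_n = 3,
                           welch = FALSE) {
  validate_parcellation(parc)
  lobes <- sort(unique(manifest$tumor_location[!is.na(manifest$tumor_location)]))
  rows <- list()

  subject_values <- function(ids, roi, metric) {
    vapply(ids, function(sid) {
      tab <- nodal[[sid]]
      tab[[metric]][tab$roi_id == roi]
    }, numeric(1))
  }

  for (lb in lobes) {
    members <- function(g) {
      if (g == "HC") manifest$subject_id[manifest$group == "HC"]
      else manifest$subject_id[manifest$group == g &
                                 !is.na(manifest$tumor_location) &
                                 manifest$tumor_location == lb]
    }
    nodes <- parc[parc$lobe == lb, c("roi_id", "name")]
    for (pr in GROUP_PAIRINGS) {
      ids_a <- members(pr[1]); ids_b <- members(pr[2])
      if (length(ids_a) < min_n || length(ids_b) < min_n) {
        gc_log("lobe %s: skipping %s (n=%d) vs %s (n=%d)",
               lb, pr[1], length(ids_a), pr[2], length(ids_b))
        next
      }
      for (m in METRIC_NAMES) {
        for (k in seq_len(nrow(nodes))) {
          cmp <- compare_groups(subject_values(ids_a, nodes$roi_id[k], m),
                                subject_values(ids_b, nodes$roi_id[k], m),
                                alpha_normality = alpha_normality,
                                welch = welch)
          r <- comparison_row(lb, nodes$roi_id[k], m, pr[1], pr[2], cmp)
          r$node_name <- nodes$name[k]
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lobe = character(), node = integer(),
                      node_name = character(), metric = character(),
                      group_a = character(), group_b = character(),
                      test_used = character(), statistic = numeric(),
                      p_raw = numeric(), p_fdr = numeric(),
                      direction = numeric(), n_a = integer(),
                      n_b = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "scope"] <- "lobe"
  fam <- interaction(out$lobe, out$metric, out$group_a, out$group_b,
                     drop = TRUE)
  out$p_fdr <- stats::ave(out$p_raw, fam, FUN = fdr_correct)
  out[, c("lobe", "node", "node_name", "metric", "group_a", "group_b",
          "test_used", "statistic", "p_raw", "p_fdr", "direction",
          "n_a", "n_b")]
}

#' Direction matrix of significant lobar effects
#'
#' Condenses a lobar analysis into an increase/decrease table for the
#' significant rows, one row per (node, metric, pairing).
#'
#' @param lobar data.frame from [lobar_analysis()].
#' @param alpha significance level on `p_fdr`.
#' @return data.frame with a `change` column (`"increase"` /
#'   `"decrease"` for `group_a` relative to `group_b`).
#' @export
lobar_direction_table <- function(lobar, alpha = 0.05) {
  sig <- lobar[!is.na(lobar$p_fdr) & lobar$p_fdr < alpha, ]
  sig$change <- ifelse(sig$direction > 0, "increase", "decrease")
  sig[, c("lobe", "node", "node_name", "metric", "group_a", "group_b",
          "p_fdr", "change")]
}

#' Seed-based group connectogram
#'
#' Second-level seed-to-ROI analysis for one group: for every target
#' ROI, the subjects' Fisher-z connectivity with the seed is tested
#' against zero with a two-sided one-sample t-test, and the N-1 target
#' p-values are Benjamini-Hochberg adjusted.  Targets with adjusted
#' p < `alpha` form the connectogram.
#'
#' @param conns named list of `conn_matrix` objects (names = subject
#'   ids).
#' @param manifest cohort manifest.
#' @param seed_roi 0-based ROI id of the seed.
#' @param group group label (needs at least 3 subjects).
#' @param alpha FDR significance level (default 0.05).
#' @return list of class `connectogram`: `seed_roi`, `group`,
#'   `targets` (data.frame with `roi_id`, `mean_z`, `statistic`,
#'   `p_raw`, `p_fdr`, `significant`), `significant_targets`, `count`.
#' @export
connectogram <- function(conns, manifest, seed_roi, group,
                         alpha = 0.05) {
  ids <- manifest$subject_id[manifest$group == group]
  if (length(ids) < 3) stop("group needs at least 3 subjects", call. = FALSE)
  n <- nrow(conns[[ids[1]]]$z)
  seed_idx <- seed_roi + 1L
  stopifnot(seed_idx >= 1, seed_idx <= n)
  targets <- setdiff(seq_len(n), seed_idx)
  zmat <- vapply(ids, function(sid) conns[[sid]]$z[seed_idx, targets],
                 numeric(length(targets)))
  zmat <- matrix(zmat, nrow = length(targets))
  res <- apply(zmat, 1, function(v) {
    if (var(v) < .Machine$double.eps) {
      c(mean(v), 0, if (abs(mean(v)) > 0) 0 else 1)
    } else {
      fit <- t.test(v, mu = 0)
      c(mean(v), unname(fit$statistic), fit$p.value)
    }
  })
  tab <- data.frame(roi_id = targets - 1L, mean_z = res[1, ],
                    statistic = res[2, ], p_raw = res[3, ])
  tab$p_fdr <- fdr_correct(tab$p_raw)
  tab$significant <- tab$p_fdr < alpha
  structure(list(seed_roi = seed_roi, group = group, targets = tab,
                 significant_targets = tab$roi_id[tab$significant],
                 count = sum(tab$significant)),
            class = "connectogram")
}

#' Compare connectogram connection counts between two groups
#'
#' Two-tailed Student t-test on the per-seed counts of significant
#' connections.
#'
#' @param counts_a,counts_b numeric vectors of counts (one per seed).
#' @return list: `statistic`, `p`, `mean_a`, `mean_b`.
#' @export
connectogram_count_compare <- function(counts_a, counts_b) {
  if (var(c(counts_a, counts_b)) < .Machine$double.eps) {
    return(list(statistic = 0, p = 1, mean_a = mean(counts_a),
                mean_b = mean(counts_b)))
  }
  fit <- t.test(counts_a, counts_b, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p = fit$p.value,
       mean_a = mean(counts_a), mean_b = mean(counts_b))
}

#' Age / tumor-size confound screen
#'
#' For every whole-brain network-mean metric, reports the Pearson
#' correlation, the covariance of the standardized variables and the
#' simple-regression slope against each covariate, flagging
#' correlations whose magnitude exceeds `corr_bound`.  Metrics are
#' standardized before screening so covariances are on a comparable
#' scale.
#'
#' @param scope_means data.frame from [cohort_scope_means()].
#' @param manifest cohort manifest (supplies `age` and `tumor_size`).
#' @param covariates covariate columns to screen (default age and
#'   tumor size; tumor size is screened over patients only).
#' @param corr_bound flag threshold on `|correlation|` (default 0.4).
#' @return data.frame: `metric`, `covariate`, `n`, `correlation`,
#'   `covariance`, `slope`, `flagged`, `note`.
#' @export
confound_screen <- function(scope_means, manifest,
                            covariates = c("age", "tumor_size"),
                            corr_bound = 0.4) {
  wb <- scope_means[scope_means$scope == "whole_brain", ]
  df <- merge(wb, manifest, by = "subject_id")
  rows <- list()
  for (cv in covariates) {
    sub <- df[!is.na(df[[cv]]), ]
    for (m in METRIC_NAMES) {
      y <- sub[[m]]; x <- sub[[cv]]
      n <- length(x)
      if (n < 3 || var(x) < .Machine$double.eps ||
          var(y) < .Machine$double.eps) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, covariate = cv, n = n, correlation = NA_real_,
          covariance = NA_real_, slope = NA_real_, flagged = FALSE,
          note = "undefined: constant covariate or metric",
          stringsAsFactors = FALSE)
        next
      }
      ys <- (y - mean(y)) / sd(y)
      xs <- (x - mean(x)) / sd(x)
      rho <- cor(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, covariate = cv, n = n, correlation = rho,
        covariance = mean(xs * ys),  # population covariance, standardized
        slope = unname(coef(lm(ys ~ x))[2]),
        flagged = abs(rho) > corr_bound, note = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
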