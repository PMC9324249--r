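#' Cohort simulation parameters
#'
#' Bundles the design of a synthetic resting-state cohort: group sizes,
#' scan length, repetition time, the baseline ROI-to-ROI correlation
#' structure and the temporal autocorrelation of the simulated BOLD
#' signal.  Defaults mirror the study design this package emulates:
#' 30 low-grade glioma (LGG), 30 high-grade glioma (HGG) and 20
#' healthy-control (HC) subjects scanned for 160 volumes at TR 2.5 s.
#'
#' The baseline correlation structure is block-wise: ROIs within the
#' same lobe and hemisphere couple at `base_r_within_lobe`, ROIs in the
#' same hemisphere but different lobes at `base_r_within_hemi`, mirror
#' (homotopic) pairs at `base_r_homotopic`, and all remaining
#' cross-hemisphere pairs at `base_r_background`.
#'
#' @param n_per_group named integer vector of subject counts for
#'   `HC`, `LGG`, `HGG` (each at least 2).
#' @param n_volumes number of timepoints per subject (>= 10).
#' @param TR repetition time in seconds.
#' @param base_r_within_lobe,base_r_within_hemi,base_r_homotopic,base_r_background
#'   baseline Pearson correlations of the four coupling classes.
#' @param ar_coeff lag-1 autoregressive coefficient of the simulated
#'   BOLD signal, in `[0, 1)`.
#' @param master_seed integer seed from which all per-subject seeds are
#'   derived.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 20, LGG = 30, HGG = 30),
                        n_volumes = 160,
                        TR = 2.5,
                        base_r_within_lobe = 0.45,
                        base_r_within_hemi = 0.06,
                        base_r_homotopic = 0.30,
                        base_r_background = 0.02,
                        ar_coeff = 0.3,
                        master_seed = 1L) {
  stopifnot(all(c("HC", "LGG", "HGG") %in% names(n_per_group)))
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group",
                                 call. = FALSE)
  if (n_volumes < 10) stop("`n_volumes` must be >= 10", call. = FALSE)
  if (ar_coeff < 0 || ar_coeff >= 1) stop("`ar_coeff` must be in [0, 1)",
                                          call. = FALSE)
  rs <- c(base_r_within_lobe, base_r_within_hemi, base_r_homotopic,
          base_r_background)
  if (any(abs(rs) >= 0.95)) stop("baseline correlations must lie in (-0.95, 0.95)",
                                 call. = FALSE)
  structure(list(n_per_group = n_per_group,
                 n_volumes = as.integer(n_volumes), TR = TR,
                 base_r_within_lobe = base_r_within_lobe,
                 base_r_within_hemi = base_r_within_hemi,
                 base_r_homotopic = base_r_homotopic,
                 base_r_background = base_r_background,
                 ar_coeff = ar_coeff,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Planted connectivity effect of a group
#'
#' Describes how one subject group's ROI-to-ROI correlation structure
#' deviates from the healthy baseline.  `delta_left_global` is added to
#' left intra-hemispheric inter-lobe couplings, `delta_local` to left
#' within-lobe couplings, and `delta_right` to all right
#' intra-hemispheric couplings.  When `tumor_location` is a lobe label,
#' the left-hemisphere deltas are restricted to couplings involving that
#' lobe (and `delta_right` to right couplings involving the homologous
#' lobe), emulating a focal lesion.
#'
#' @param group `"HC"`, `"LGG"` or `"HGG"`.
#' @param tumor_location lobe label or `NA` for a hemisphere-wide
#'   effect.
#' @param delta_left_global,delta_right,delta_local signed correlation
#'   increments.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(group,
                        tumor_location = NA_character_,
                        delta_left_global = 0,
                        delta_right = 0,
                        delta_local = 0) {
  group <- match.arg(group, c("HC", "LGG", "HGG"))
  if (group == "HC" &&
      any(c(delta_left_global, delta_right, delta_local) != 0)) {
    stop("HC must have all deltas equal to 0", call. = FALSE)
  }
  if (!is.na(tumor_location) && !tumor_location %in% LOBE_LABELS) {
    stop("unknown `tumor_location`", call. = FALSE)
  }
  structure(list(group = group, tumor_location = tumor_location,
                 delta_left_global = delta_left_global,
                 delta_right = delta_right,
                 delta_local = delta_local),
            class = "effect_spec")
}

#' Default planted group effects
#'
#' The package's reference effect configuration: LGG shifts coupling
#' weight in the left hemisphere from within-lobe to between-lobe
#' connections (integration gain at the expense of local clustering),
#' and HGG attenuates right-hemisphere coupling (remote disconnection,
#' a diaschisis-like effect).  HC is the unperturbed baseline.
#'
#' @return named list of [effect_spec()] objects.
#' @export
default_effects <- function() {
  list(
    HC  = effect_spec("HC"),
    LGG = effect_spec("LGG", delta_left_global = 0.08, delta_local = -0.33),
    HGG = effect_spec("HGG", delta_right = -0.10)
  )
}

#' Build the ROI-to-ROI covariance matrix of one group
#'
#' Constructs the block-structured correlation matrix implied by a
#' cohort spec and one group's planted effect: unit diagonal, baseline
#' values per coupling class, plus the effect's deltas.  If the result
#' is not positive definite it is repaired by clipping eigenvalues at
#' `1e-8` and rescaling back to unit diagonal; the repair is logged and
#' flagged in the `"repaired"` attribute.
#'
#' @param parc parcellation table.
#' @param spec [cohort_spec()].
#' @param effect [effect_spec()].
#' @return N x N covariance (correlation) matrix with attribute
#'   `"repaired"` (logical).
#' @export
build_covariance <- function(parc, spec, effect) {
  validate_parcellation(parc)
  stopifnot(inherits(spec, "cohort_spec"), inherits(effect, "effect_spec"))
  parc <- parc[order(parc$roi_id), ]
  n <- nrow(parc)
  hemi <- parc$hemisphere
  lobe <- parc$lobe

  same_hemi <- outer(hemi, hemi, "==")
  same_lobe <- outer(lobe, lobe, "==")
  S <- matrix(spec$base_r_background, n, n)
  S[same_hemi] <- spec$base_r_within_hemi
  S[same_hemi & same_lobe] <- spec$base_r_within_lobe
  hp <- homotopic_pairs(parc)
  if (nrow(hp) > 0) {
    idx <- cbind(hp[, 1] + 1L, hp[, 2] + 1L)
    S[idx] <- spec$base_r_homotopic
    S[idx[, 2:1, drop = FALSE]] <- spec$base_r_homotopic
  }

  left <- hemi == "L"
  right <- hemi == "R"
  in_lobe <- function(side) {
    if (is.na(effect$tumor_location)) side
    else side & lobe == effect$tumor_location
  }
  # a pair is touched by a focal effect if at least one endpoint lies in
  # the tumor lobe (homologous lobe on the right)
  touch <- function(side) {
    m <- in_lobe(side)
    outer(m, side, "&") | outer(side, m, "&")
  }
  left_pairs <- outer(left, left, "&")
  right_pairs <- outer(right, right, "&")
  S[left_pairs & !same_lobe & touch(left)] <-
    S[left_pairs & !same_lobe & touch(left)] + effect$delta_left_global
  S[left_pairs & same_lobe & touch(left)] <-
    S[left_pairs & same_lobe & touch(left)] + effect$delta_local
  S[right_pairs & touch(right)] <-
    S[right_pairs & touch(right)] + effect$delta_right
  diag(S) <- 1
  S <- (S + t(S)) / 2

  off <- S[upper.tri(S)]
  if (any(abs(off) >= 0.95)) {
    stop("effect deltas push correlations outside (-0.95, 0.95)",
         call. = FALSE)
  }

  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    vals <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    repaired <- TRUE
    gc_log("covariance for group %s was not positive definite; repaired by eigenvalue clipping",
           effect$group)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("covariance repair failed: matrix remains indefinite",
           call. = FALSE)
    }
  }
  attr(S, "repaired") <- repaired
  S
}

#' Simulate one subject's ROI timeseries
#'
#' Draws a stationary Gaussian process whose cross-sectional covariance
#' equals `cov` and whose temporal autocorrelation follows an AR(1)
#' recursion with coefficient `ar_coeff`: correlated innovations are
#' scaled by `sqrt(1 - ar_coeff^2)` so the spatial covariance is
#' preserved exactly in expectation at every timepoint.
#'
#' @param cov positive-definite N x N covariance matrix (or its upper
#'   Cholesky factor with attribute `"chol"` set to `TRUE`).
#' @param n_volumes number of timepoints.
#' @param ar_coeff AR(1) coefficient in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return `n_volumes` x N numeric matrix.
#' @export
simulate_timeseries <- function(cov, n_volumes, ar_coeff, seed) {
  L <- if (isTRUE(attr(cov, "chol"))) cov else chol(cov)
  n <- ncol(L)
  stopifnot(n_volumes >= 1, ar_coeff >= 0, ar_coeff < 1)
  set.seed(as.integer(seed))
  innov <- matrix(rnorm(n_volumes * n), n_volumes, n) %*% L
  x <- matrix(0, n_volumes, n)
  x[1, ] <- innov[1, ]
  if (n_volumes > 1) {
    s <- sqrt(1 - ar_coeff^2)
    for (t in 2:n_volumes) {
      x[t, ] <- ar_coeff * x[t - 1, ] + s * innov[t, ]
    }
  }
  x
}

# default single-location mix per group, proportional to the lobar
# involvement reported for left-hemispheric gliomas (frontal, temporal,
# parietal, insular); HC carry no location
#' @noRd
default_location_weights <- function() {
  list(
    LGG = c(frontal = 15, temporal = 13, parietal = 4, insular = 12),
    HGG = c(frontal = 5, temporal = 16, parietal = 11, insular = 5)
  )
}

#' @noRd
assign_locations <- function(group, n, weights) {
  if (group == "HC" || is.null(weights[[group]])) {
    return(rep(NA_character_, n))
  }
  w <- weights[[group]]
  rep(names(w), apportion(n, w))
}

#' Generate a full synthetic cohort
#'
#' Produces one [simulate_timeseries()] draw per subject, with group
#' membership, tumor location, age and tumor size attached.  Subjects of
#' the same group (and, for focal effects, tumor location) share a
#' covariance matrix; each subject's seed is derived deterministically
#' from `spec$master_seed` and the subject id, so the cohort is a pure
#' function of its arguments and any subject can be regenerated alone.
#'
#' Ages are Gaussian with group means 48 (HC), 40 (LGG) and 62 (HGG)
#' years (sd 10); tumor sizes (product of perpendicular diameters,
#' cm^2) are Gaussian mean 12, sd 6, truncated above 0.5, drawn for
#' patients only.
#'
#' @param parc parcellation table.
#' @param spec [cohort_spec()].
#' @param effects named list of [effect_spec()] objects or a flat list
#'   of (group, location)-specific effects; subjects match the most
#'   specific applicable effect, falling back to a zero-delta baseline.
#' @param location_weights per-group named weights used to apportion
#'   tumor locations deterministically (default mirrors the reference
#'   cohort's lobar mix); pass `NULL` for no locations.
#' @return list of class `cohort`: elements `subjects` (list of
#'   per-subject records with `data`, `subject_id`, `group`,
#'   `tumor_location`, `age`, `tumor_size`, `seed`), `parcellation`,
#'   `spec`, `effects`.
#' @export
generate_cohort <- function(parc, spec = cohort_spec(),
                            effects = default_effects(),
                            location_weights = default_location_weights()) {
  validate_parcellation(parc)
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, TRUE, "effect_spec")))

  groups <- c("HC", "LGG", "HGG")
  # most specific effect for a (group, location) pair
  find_effect <- function(group, location) {
    hit <- NULL
    for (e in effects) {
      if (e$group != group) next
      if (!is.na(e$tumor_location)) {
        if (!is.na(location) && e$tumor_location == location) return(e)
      } else if (is.null(hit)) hit <- e
    }
    hit %||% effect_spec(group)
  }

  chol_cache <- list()
  cov_chol <- function(eff) {
    key <- paste(eff$group, eff$tumor_location, eff$delta_left_global,
                 eff$delta_right, eff$delta_local, sep = "|")
    if (is.null(chol_cache[[key]])) {
      S <- build_covariance(parc, spec, eff)
      U <- chol(S)
      attr(U, "chol") <- TRUE
      chol_cache[[key]] <<- U
    }
    chol_cache[[key]]
  }

  age_mean <- c(HC = 48, LGG = 40, HGG = 62)
  subjects <- list()
  for (g in groups) {
    n_g <- spec$n_per_group[[g]]
    locs <- assign_locations(g, n_g, location_weights)
    for (i in seq_len(n_g)) {
      sid <- sprintf("%s_%02d", g, i)
      seed <- derive_seed(spec$master_seed, sid)
      eff <- find_effect(g, locs[i])
      ts <- simulate_timeseries(cov_chol(eff), spec$n_volumes,
                                spec$ar_coeff, seed)
      set.seed(derive_seed(seed, "covariates"))
      age <- rnorm(1, age_mean[[g]], 10)
      size <- NA_real_
      if (g != "HC") {
        repeat {
          size <- rnorm(1, 12, 6)
          if (size > 0.5) break
        }
      }
      subjects[[sid]] <- list(data = ts, subject_id = sid, group = g,
                              tumor_location = locs[i], age = age,
                              tumor_size = size, seed = seed)
    }
  }
  structure(list(subjects = subjects, parcellation = parc, spec = spec,
                 effects = effects),
            class = "cohort")
}

#' Cohort manifest as a data.frame
#'
#' @param cohort object from [generate_cohort()] (or [read_cohort()]).
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `tumor_location`, `age`, `tumor_size`, `seed`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               tumor_location = s$tumor_location %||% NA_character_,
               age = s$age, tumor_size = s$tumor_size, seed = s$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a cohort to a directory of TSV files
#'
#' Writes `parcellation.tsv`, `manifest.tsv` and one
#' `timeseries/<subject_id>.tsv` (timepoints x ROIs) per subject.
#'
#' @param cohort cohort object.
#' @param dir output directory (created if needed).
#' @return `read_cohort` returns a `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  man <- cohort_manifest(cohort)
  man$file <- file.path("timeseries", paste0(man$subject_id, ".tsv"))
  write_tsv(man, file.path(dir, "manifest.tsv"))
  for (s in cohort$subjects) {
    m <- s$data
    colnames(m) <- cohort$parcellation$roi_id[order(cohort$parcellation$roi_id)]
    write_tsv(as.data.frame(m),
              file.path(dir, "timeseries", paste0(s$subject_id, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"))
  man <- read_tsv(file.path(dir, "manifest.tsv"))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    m <- as.matrix(read_tsv(file.path(dir, man$file[i])))
    dimnames(m) <- NULL
    list(data = m, subject_id = man$subject_id[i], group = man$group[i],
         tumor_location = if (is.na(man$tumor_location[i])) NA_character_
                          else man$tumor_location[i],
         age = man$age[i], tumor_size = man$tumor_size[i],
         seed = man$seed[i])
  })
  names(subjects) <- man$subject_id
  structure(list(subjects = subjects, parcellation = parc, spec = NULL,
                 effects = NULL),
            class = "cohort")
}
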