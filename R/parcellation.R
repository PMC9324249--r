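#' Lobe labels recognised by the parcellation
#'
#' @format character vector of lobe labels.
#' @export
LOBE_LABELS <- c("frontal", "temporal", "parietal", "insular",
                 "occipital", "other")

#' Default lobe composition of a hemisphere
#'
#' Approximate relative sizes (parcel counts) of the cortical lobes in a
#' whole-brain anatomical parcellation; used to split each hemisphere of
#' a synthetic atlas into lobar subnetworks.
#'
#' @format named numeric vector summing to 1.
#' @export
DEFAULT_LOBE_FRACTIONS <- c(frontal = 0.25, temporal = 0.22,
                            parietal = 0.18, insular = 0.10,
                            occipital = 0.15, other = 0.10)

# largest-remainder apportionment of n items over fractions
#' @noRd
apportion <- function(n, fractions) {
  fractions <- fractions / sum(fractions)
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Build a synthetic brain parcellation table
#'
#' Creates a deterministic table of regions of interest (ROIs) split
#' evenly between the left and right hemispheres, with each hemisphere
#' apportioned across lobes according to `lobe_fractions`.  ROIs are
#' homotopically paired: the k-th ROI of a lobe in the left hemisphere
#' is the mirror of the k-th ROI of the same lobe on the right.
#'
#' @param n_roi total number of ROIs (even, at least 4); the default 136
#'   matches a standard whole-brain anatomical atlas.
#' @param lobe_fractions named numeric vector of per-lobe fractions
#'   (names from [LOBE_LABELS]); normalised internally.
#' @return data.frame with columns `roi_id` (0-based integer), `name`,
#'   `hemisphere` (`"L"`/`"R"`) and `lobe`.
#' @examples
#' parc <- make_parcellation(20)
#' table(parc$hemisphere)
#' @export
make_parcellation <- function(n_roi = 136,
                              lobe_fractions = DEFAULT_LOBE_FRACTIONS) {
  if (!is.numeric(n_roi) || length(n_roi) != 1L || n_roi < 4 ||
      n_roi %% 2 != 0) {
    stop("`n_roi` must be a single even integer >= 4", call. = FALSE)
  }
  if (is.null(names(lobe_fractions)) ||
      !all(names(lobe_fractions) %in% LOBE_LABELS)) {
    stop("`lobe_fractions` must be named with lobe labels", call. = FALSE)
  }
  lobe_fractions <- lobe_fractions[lobe_fractions > 0]
  per_hemi <- n_roi / 2L
  counts <- apportion(per_hemi, lobe_fractions)
  lobes <- rep(names(lobe_fractions), counts)
  idx_in_lobe <- unlist(lapply(counts, seq_len), use.names = FALSE)
  hemi_tab <- function(h) {
    data.frame(
      name = sprintf("%s_%s_%02d", h, lobes, idx_in_lobe),
      hemisphere = h,
      lobe = lobes,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(hemi_tab("L"), hemi_tab("R"))
  out <- cbind(roi_id = seq_len(nrow(out)) - 1L, out)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @noRd
validate_parcellation <- function(parc) {
  stopifnot(is.data.frame(parc),
            all(c("roi_id", "name", "hemisphere", "lobe") %in% names(parc)))
  if (anyDuplicated(parc$roi_id) ||
      !identical(as.integer(sort(parc$roi_id)),
                 seq_len(nrow(parc)) - 1L)) {
    stop("parcellation roi_ids must be unique and contiguous from 0",
         call. = FALSE)
  }
  if (!all(parc$hemisphere %in% c("L", "R", "M"))) {
    stop("hemisphere labels must be L, R or M", call. = FALSE)
  }
  if (!all(parc$lobe %in% LOBE_LABELS)) {
    stop("unknown lobe label in parcellation", call. = FALSE)
  }
  invisible(parc)
}

#' Homotopic ROI pairs of a parcellation
#'
#' Pairs left/right ROIs that share a lobe and within-lobe position
#' (mirror regions across the midline).
#'
#' @param parc parcellation table from [make_parcellation()] or
#'   [read_parcellation()].
#' @return two-column integer matrix of 0-based `roi_id`s (`left`,
#'   `right`); zero rows if the parcellation has no mirrored pairs.
#' @export
homotopic_pairs <- function(parc) {
  validate_parcellation(parc)
  key <- function(h) {
    p <- parc[parc$hemisphere == h, ]
    p <- p[order(p$lobe, p$name), ]
    split(p$roi_id, p$lobe)
  }
  lk <- key("L"); rk <- key("R")
  pairs <- lapply(intersect(names(lk), names(rk)), function(lb) {
    k <- min(length(lk[[lb]]), length(rk[[lb]]))
    if (k == 0) return(NULL)
    cbind(left = lk[[lb]][seq_len(k)], right = rk[[lb]][seq_len(k)])
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) out <- matrix(integer(), 0, 2,
                                  dimnames = list(NULL, c("left", "right")))
  out
}

#' Write / read a parcellation table as TSV
#'
#' @param parc parcellation table.
#' @param path file path.
#' @return `read_parcellation` returns the validated parcellation.
#' @export
write_parcellation <- function(parc, path) {
  validate_parcellation(parc)
  write_tsv(parc[, c("roi_id", "name", "hemisphere", "lobe")], path)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  parc <- read_tsv(path)
  parc$roi_id <- as.integer(parc$roi_id)
  class(parc) <- c("parcellation", "data.frame")
  validate_parcellation(parc)
  parc
}
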