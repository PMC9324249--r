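#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable 31-bit string hash
#'
#' Deterministic polynomial rolling hash of a character string, reduced
#' modulo 2^31 - 1.  Used to derive per-subject simulation seeds from a
#' master seed so that any subject can be regenerated in isolation.
#'
#' @param x character scalar.
#' @return integer in `[0, 2^31 - 2]`.
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% m
  as.integer(h)
}

#' @noRd
derive_seed <- function(master_seed, subject_id) {
  as.integer((as.numeric(master_seed) + stable_hash(subject_id)) %% 2147483647)
}

#' @noRd
gc_log <- function(fmt, ...) {
  message(sprintf(paste0("[gliomaconn] ", fmt), ...))
}

#' @noRd
write_tsv <- function(x, path, row.names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row.names,
              col.names = TRUE)
}

#' @noRd
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
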