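`%||%` <- function(x, y) if (is.null(x)) y else x

#' Developmental domains used throughout the package
#'
#' The four 34-item scales of a milestone-based screening instrument:
#' gross motor, fine motor, language, and social development.
#'
#' @return Character vector of the four domain names.
#' @export
milestone_domains <- function() {
  c("gross_motor", "fine_motor", "language", "social")
}

outcome_levels <- function() {
  c("pass", "fail", "dont_know", "not_administered")
}

# Derive a stream-specific seed from a run seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + 10007L * as.integer(offset)) %% 2147483587L + 1L
}

# Stable content hash of an R object (djb2 over its deparsed form), used for
# run manifests so that reruns with identical configuration are detectable.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Expand a scalar or per-domain named value to a named vector over `domains`.
per_domain <- function(x, domains, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(x, length(domains)), domains))
  }
  if (is.null(names(x)) && length(x) == length(domains)) {
    return(stats::setNames(x, domains))
  }
  missing <- setdiff(domains, names(x))
  if (length(missing)) {
    stop(sprintf("%s must be a scalar or named per domain (missing: %s)",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  x[domains]
}
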