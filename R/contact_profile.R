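# ContactProfile: ordered (separation, frequency, SEM) observations from
# one locus / set of 3C anchors, with cell-type and TAD-class metadata.

.TAD_CLASSES <- c("gene-rich", "gene-poor", "gene-desert", "unknown")

#' Build a 3C contact profile
#'
#' A contact profile holds ordered quantitative-3C observations — genomic
#' separation (kb), relative contact frequency and, optionally, its
#' standard error — together with metadata used by the fitting and
#' domain-statistics stages. Profiles pooled across several anchors of the
#' same TAD class are the fitting unit for the mouse-style analyses.
#'
#' @param separation_kb Genomic separations in kb, strictly positive.
#' @param frequency Relative contact frequencies, non-negative.
#' @param sem Standard errors of the mean (same scale as `frequency`),
#'   non-negative; `NA` when unavailable.
#' @param anchor_id,locus Character labels (recycled) identifying the 3C
#'   anchor primer and the locus.
#' @param cell_type Optional cell-type label.
#' @param tad_class One of `"gene-rich"`, `"gene-poor"`, `"gene-desert"`,
#'   `"unknown"`.
#' @param fixed_L Optional linear mass density (nm/kb) to be held fixed in
#'   fits of this profile (e.g. derived from the cell type's nucleosome
#'   repeat length via [linear_density_from_nrl()]).
#' @return A `contact_profile`: a `data.frame` with columns `anchor_id`,
#'   `locus`, `separation_kb`, `frequency`, `sem` and metadata attributes
#'   `cell_type`, `tad_class`, `fixed_L`.
#' @examples
#' contact_profile(c(5, 10, 20), c(1.2, 0.8, 0.5), sem = c(.1, .1, .05))
#' @export
contact_profile <- function(separation_kb, frequency, sem = NA_real_,
                            anchor_id = "anchor", locus = "locus",
                            cell_type = NA_character_,
                            tad_class = "unknown", fixed_L = NULL) {
  stopifnot(is.numeric(separation_kb), is.numeric(frequency))
  n <- length(separation_kb)
  if (length(frequency) != n) {
    stop("`separation_kb` and `frequency` must have equal length")
  }
  if (any(!is.finite(separation_kb)) || any(separation_kb <= 0)) {
    stop("separations must be finite and strictly positive")
  }
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequencies must be finite and non-negative")
  }
  sem <- rep_len(as.numeric(sem), n)
  if (any(sem < 0, na.rm = TRUE)) stop("`sem` must be non-negative")
  tad_class <- match.arg(tad_class, .TAD_CLASSES)
  if (!is.null(fixed_L)) {
    stopifnot(is.numeric(fixed_L), length(fixed_L) == 1L, fixed_L > 0)
  }
  out <- data.frame(
    anchor_id = rep_len(as.character(anchor_id), n),
    locus = rep_len(as.character(locus), n),
    separation_kb = as.numeric(separation_kb),
    frequency = as.numeric(frequency),
    sem = sem,
    stringsAsFactors = FALSE
  )
  structure(out,
    cell_type = cell_type, tad_class = tad_class, fixed_L = fixed_L,
    class = c("contact_profile", "data.frame")
  )
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf(
    "<contact_profile> %d observations, %d anchor(s), tad_class=%s%s\n",
    nrow(x), length(unique(x$anchor_id)), attr(x, "tad_class"),
    if (is.null(attr(x, "fixed_L"))) "" else
      sprintf(", fixed L=%.4g nm/kb", attr(x, "fixed_L"))
  ))
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# Pool several profiles into one (used to compile anchors of one TAD class).
#' Pool contact profiles
#'
#' Concatenates several [contact_profile()]s (e.g. all anchors of one TAD
#' class) into a single profile for joint fitting. Metadata is taken from
#' the first profile; differing `tad_class` values collapse to `"unknown"`.
#'
#' @param ... `contact_profile` objects, or a single list of them.
#' @return A pooled `contact_profile`.
#' @export
pool_profiles <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) &&
      !inherits(ps[[1]], "contact_profile")) {
    ps <- ps[[1]]
  }
  stopifnot(length(ps) >= 1L,
            all(vapply(ps, inherits, logical(1), "contact_profile")))
  classes <- unique(vapply(ps, attr, character(1), "tad_class"))
  df <- do.call(rbind, lapply(ps, as.data.frame))
  contact_profile(
    df$separation_kb, df$frequency, sem = df$sem,
    anchor_id = df$anchor_id, locus = df$locus,
    cell_type = attr(ps[[1]], "cell_type"),
    tad_class = if (length(classes) == 1L) classes else "unknown",
    fixed_L = attr(ps[[1]], "fixed_L")
  )
}
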