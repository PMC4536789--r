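# Supranucleosomal separation-distance domains: alternating windows of
# genomic separation within which mean contact frequencies are
# alternately higher and lower — the observable signature of the
# statistical-helix modulation — and Mann-Whitney U tests between
# adjacent windows.

.ROMAN <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")

#' Supranucleosomal domain scheme
#'
#' Defines the consecutive separation-distance windows (left-closed,
#' right-open, in kb) used to bin observations before testing adjacent
#' windows. Two standard schemes are built in: `"gene_rich_poor"`
#' (35-kb steps: 0-35, 35-70, ..., 205-250 kb, domains I-VI) used for
#' gene-rich and gene-poor loci, and `"gene_desert"` (25-kb steps to
#' 150 kb). A boundary value belongs to the upper domain (half-open
#' convention).
#'
#' @param scheme_id `"gene_rich_poor"`, `"gene_desert"` or `"custom"`.
#' @param boundaries For `"custom"`: strictly increasing kb boundaries
#'   (`>= 2` values).
#' @return A list of class `domain_scheme` with `boundaries` and domain
#'   `labels` (Roman numerals).
#' @examples
#' domain_scheme("gene_rich_poor")
#' domain_scheme("custom", boundaries = c(0, 50, 100))
#' @export
domain_scheme <- function(scheme_id = c("gene_rich_poor", "gene_desert",
                                        "custom"),
                          boundaries = NULL) {
  scheme_id <- match.arg(scheme_id)
  if (scheme_id == "gene_rich_poor") {
    boundaries <- c(0, 35, 70, 115, 160, 205, 250)
  } else if (scheme_id == "gene_desert") {
    boundaries <- seq(0, 150, by = 25)
  } else {
    if (is.null(boundaries)) stop("custom schemes need `boundaries`")
  }
  stopifnot(is.numeric(boundaries), length(boundaries) >= 2L,
            all(diff(boundaries) > 0))
  n_dom <- length(boundaries) - 1L
  if (n_dom > length(.ROMAN)) stop("too many domains (max 10)")
  structure(
    list(scheme_id = scheme_id, boundaries = as.numeric(boundaries),
         labels = .ROMAN[seq_len(n_dom)]),
    class = "domain_scheme"
  )
}

#' @export
print.domain_scheme <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf("<domain_scheme: %s>\n", x$scheme_id))
  cat(paste(sprintf("  %-4s [%g, %g) kb", x$labels, b[-length(b)], b[-1]),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Assign observations to supranucleosomal domains
#'
#' Labels each separation by its domain under the half-open interval
#' convention `[b_i, b_{i+1})`; separations outside all intervals are
#' labelled `"outside"`.
#'
#' @param x Numeric separations in kb, or a [contact_profile()].
#' @param scheme A [domain_scheme()].
#' @return Character vector of domain labels.
#' @examples
#' assign_domains(c(30, 35, 40, 400), domain_scheme("gene_rich_poor"))
#' @export
assign_domains <- function(x, scheme = domain_scheme("gene_rich_poor")) {
  stopifnot(inherits(scheme, "domain_scheme"))
  s <- if (inherits(x, "contact_profile")) x$separation_kb else x
  stopifnot(is.numeric(s))
  idx <- findInterval(s, scheme$boundaries)
  out <- rep("outside", length(s))
  inside <- idx >= 1 & idx <= length(scheme$labels) &
    s < scheme$boundaries[length(scheme$boundaries)]
  out[inside] <- scheme$labels[idx[inside]]
  out
}

.pool_observations <- function(profiles) {
  if (inherits(profiles, "contact_profile")) return(as.data.frame(profiles))
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, logical(1), "contact_profile")))
  do.call(rbind, lapply(profiles, as.data.frame))
}

#' Per-domain mean contact frequencies
#'
#' Pools the observations of one or more profiles and reports, for every
#' domain of the scheme, the arithmetic mean frequency and the number of
#' observations. Empty domains are kept with `n = 0` and `NaN` mean so
#' that gaps are visible rather than silently dropped.
#'
#' @param profiles A [contact_profile()] or list of them.
#' @param scheme A [domain_scheme()].
#' @return A `data.frame` with columns `domain`, `mean_frequency`, `n`.
#' @export
domain_means <- function(profiles, scheme = domain_scheme("gene_rich_poor")) {
  obs <- .pool_observations(profiles)
  lab <- assign_domains(obs$separation_kb, scheme)
  out <- do.call(rbind, lapply(scheme$labels, function(d) {
    f <- obs$frequency[lab == d]
    data.frame(domain = d, mean_frequency = mean(f), n = length(f))
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sample rank test (Mann-Whitney U / unpaired Wilcoxon rank-sum),
#' exact by enumeration of the U distribution when the combined sample
#' size is at most `exact_max_n` and there are no ties, otherwise the
#' normal approximation with tie and continuity correction. Two samples
#' whose pooled values are all identical give `p = 1`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max_n Combined-size threshold for the exact test.
#' @return A list with `u` (the U statistic of `x`), `p_value`, `n_x`,
#'   `n_y`, and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact two-sided p = 1/3
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided",
                           exact_max_n = 12) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (all(pooled == pooled[1])) {
    return(list(u = u, p_value = 1, n_x = length(x), n_y = length(y),
                method = "degenerate (all values equal)"))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_max_n
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE
  ))
  list(u = unname(ht$statistic), p_value = ht$p.value,
       n_x = length(x), n_y = length(y),
       method = if (exact) "exact" else "normal approximation")
}

#' Significance stars for a p-value
#'
#' Two annotation conventions used on the contact-frequency figures:
#' `"two_level"` marks `0.01 < p < 0.05` with `**` and `p < 0.01` with
#' `***`; `"three_level"` marks `0.01 < p < 0.05` with `*`,
#' `0.001 < p < 0.01` with `**` and `p < 0.001` with `***`. All other
#' p-values (including the boundary values themselves) give `""`.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param convention `"two_level"` or `"three_level"`.
#' @return Character vector of star annotations.
#' @examples
#' star_annotation(0.03, "two_level")   # "**"
#' star_annotation(0.03, "three_level") # "*"
#' @export
star_annotation <- function(p, convention = c("two_level", "three_level")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (convention == "two_level") {
    ifelse(p < 0.01, "***", ifelse(p > 0.01 & p < 0.05, "**", ""))
  } else {
    ifelse(p < 0.001, "***",
           ifelse(p > 0.001 & p < 0.01, "**",
                  ifelse(p > 0.01 & p < 0.05, "*", "")))
  }
}

#' Mann-Whitney tests between adjacent supranucleosomal domains
#'
#' Pools observations, bins them into the scheme's domains, and tests
#' every adjacent domain pair for a difference in contact frequencies
#' (two-sided by default; the direction of the alternation is not assumed
#' in advance). Pairs with an empty side are kept in the table but
#' flagged `skipped` with `NA` statistics. P-values are reported raw
#' (no multiplicity correction across the adjacent pairs).
#'
#' @param profiles A [contact_profile()] or list of them.
#' @param scheme A [domain_scheme()].
#' @param convention Star convention, see [star_annotation()].
#' @param alternative Passed to [mann_whitney_u()].
#' @return A `data.frame` with one row per adjacent pair: `pair`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `u_stat`, `p_value`, `stars`,
#'   `skipped`.
#' @export
adjacent_domain_tests <- function(profiles,
                                  scheme = domain_scheme("gene_rich_poor"),
                                  convention = c("two_level", "three_level"),
                                  alternative = "two.sided") {
  convention <- match.arg(convention)
  obs <- .pool_observations(profiles)
  lab <- assign_domains(obs$separation_kb, scheme)
  labs <- scheme$labels
  rows <- lapply(seq_len(length(labs) - 1L), function(i) {
    a <- obs$frequency[lab == labs[i]]
    b <- obs$frequency[lab == labs[i + 1L]]
    base <- data.frame(
      pair = paste(labs[i], labs[i + 1L], sep = "-"),
      mean_a = mean(a), mean_b = mean(b),
      n_a = length(a), n_b = length(b),
      u_stat = NA_real_, p_value = NA_real_, stars = "",
      skipped = length(a) == 0 || length(b) == 0,
      stringsAsFactors = FALSE
    )
    if (!base$skipped) {
      mw <- mann_whitney_u(a, b, alternative = alternative)
      base$u_stat <- mw$u
      base$p_value <- mw$p_value
      base$stars <- star_annotation(mw$p_value, convention)
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
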