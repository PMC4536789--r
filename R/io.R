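# Readers and writers for the pipeline's plain-text formats: contact
# profile TSVs, BED4 annotation tracks, contact maps (sparse triples or
# dense matrix), fit tables (TSV) and fit results (JSON).
#
# Conventions: BED coordinates are 0-based half-open and become 1-based
# closed GRanges in memory; separations are written with 3-decimal kb
# precision; frequencies at full precision.

#' Read a contact-profile TSV
#'
#' Expects a tab-separated file with header columns `anchor_id`, `locus`,
#' `separation_kb`, `frequency` and optionally `sem`. Rows with missing,
#' unparseable or non-positive separations (or negative frequencies) are
#' rejected with an error naming the offending line. A missing `sem`
#' column loads with `NA` SEMs, so fits default to uniform weights.
#'
#' @param path File path.
#' @param ... Metadata passed to [contact_profile()] (`cell_type`,
#'   `tad_class`, `fixed_L`).
#' @return A [contact_profile()].
#' @export
read_contact_profile <- function(path, ...) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- c("anchor_id", "locus", "separation_kb", "frequency")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric `%s` at line %s of %s", col,
                   paste(bad + 1L, collapse = ", "), path))
    }
    v
  }
  sep <- num("separation_kb")
  bad <- which(sep <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive separation_kb at line %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  }
  freq <- num("frequency")
  bad <- which(freq < 0)
  if (length(bad)) {
    stop(sprintf("negative frequency at line %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  }
  sem <- if ("sem" %in% names(df)) {
    suppressWarnings(as.numeric(df$sem))
  } else NA_real_
  contact_profile(sep, freq, sem = sem, anchor_id = df$anchor_id,
                  locus = df$locus, ...)
}

#' Write a contact profile as TSV
#'
#' @param profile A [contact_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_profile <- function(profile, path) {
  stopifnot(inherits(profile, "contact_profile"))
  out <- data.frame(
    anchor_id = profile$anchor_id,
    locus = profile$locus,
    separation_kb = sprintf("%.3f", profile$separation_kb),
    frequency = format(profile$frequency, digits = 17, trim = TRUE,
                       scientific = NA),
    sem = ifelse(is.na(profile$sem), "NA",
                 format(profile$sem, digits = 17, trim = TRUE,
                        scientific = NA))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.EPIGENETIC_ALIASES <- c(
  red = "D1", black = "D2", blue = "D3", green = "D4",
  D1 = "D1", D2 = "D2", D3 = "D3", D4 = "D4"
)

#' Read a BED4 annotation track
#'
#' Reads TAD or epigenetic-domain intervals from a BED4 file (0-based
#' half-open; the name column holds the TAD id or the epigenetic class,
#' with colour aliases red/black/blue/green normalized to D1/D2/D3/D4).
#' Intervals of one track must not overlap.
#'
#' @param path BED file path.
#' @param kind `"tad"` or `"epigenetic"`.
#' @return A `GRanges` with metadata column `name`.
#' @export
read_bed_annotation <- function(path, kind = c("tad", "epigenetic")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$name) ||
      anyNA(S4Vectors::mcols(gr)$name)) {
    stop("BED4 input required: every interval needs a name (column 4)")
  }
  if (any(GenomicRanges::width(gr) < 1)) {
    stop("intervals with start >= end are not allowed")
  }
  if (!GenomicRanges::isDisjoint(gr)) {
    stop("overlapping intervals in one annotation track are not allowed")
  }
  if (kind == "epigenetic") {
    nm <- tolower(S4Vectors::mcols(gr)$name)
    nm[nm %in% c("d1", "d2", "d3", "d4")] <- toupper(nm[nm %in%
                                                     c("d1", "d2", "d3", "d4")])
    mapped <- .EPIGENETIC_ALIASES[ifelse(nm %in% names(.EPIGENETIC_ALIASES),
                                         nm, NA_character_)]
    unknown <- is.na(mapped)
    if (any(unknown)) {
      stop("unknown epigenetic class label(s): ",
           paste(unique(S4Vectors::mcols(gr)$name[unknown]), collapse = ", "))
    }
    S4Vectors::mcols(gr)$name <- unname(mapped)
  }
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["name"]
  gr
}

#' Write an annotation track as BED4
#'
#' @param gr A `GRanges` with metadata column `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_annotation <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"),
            !is.null(S4Vectors::mcols(gr)$name))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # back to 0-based half-open
    end = GenomicRanges::end(gr),
    name = S4Vectors::mcols(gr)$name
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binned contact map
#'
#' Accepts either the sparse form — a `# bin_size_kb=<n> ...` comment
#' line, a header `chrom bin_i bin_j value`, then tab-separated triples
#' with 0-based bin indices — or a dense whitespace-separated square
#' matrix (optionally preceded by the same comment line). Negative
#' values and bin sizes conflicting with `bin_size_kb` are rejected.
#'
#' @param path File path.
#' @param chrom Chromosome id for dense input (sparse input carries its
#'   own `chrom` column).
#' @param bin_size_kb Bin size override; must agree with the file header
#'   when both are present.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, chrom = NULL, bin_size_kb = NULL) {
  lines <- readLines(path)
  header_bin <- header_nbins <- NULL
  while (length(lines) && startsWith(lines[1], "#")) {
    toks <- regmatches(lines[1],
                       gregexpr("[A-Za-z_]+=[-0-9.eE+]+", lines[1]))[[1]]
    kv <- strsplit(toks, "=")
    for (p in kv) {
      if (p[1] == "bin_size_kb") header_bin <- as.numeric(p[2])
      if (p[1] == "n_bins") header_nbins <- as.integer(p[2])
    }
    lines <- lines[-1]
  }
  if (!is.null(bin_size_kb) && !is.null(header_bin) &&
      bin_size_kb != header_bin) {
    stop(sprintf("bin size mismatch: file declares %g kb, caller asked %g kb",
                 header_bin, bin_size_kb))
  }
  bs <- if (!is.null(header_bin)) header_bin else
    if (!is.null(bin_size_kb)) bin_size_kb else 5
  if (!length(lines)) stop("empty contact-map file: ", path)
  first <- strsplit(lines[1], "\t")[[1]]
  if (identical(first[1:4], c("chrom", "bin_i", "bin_j", "value"))) {
    df <- utils::read.table(text = lines, header = TRUE, sep = "\t")
    if (any(df$value < 0)) stop("negative contact values are not allowed")
    chroms <- unique(df$chrom)
    if (length(chroms) != 1L) {
      stop("a contact map holds one chromosome; found: ",
           paste(chroms, collapse = ", "))
    }
    contact_map(df[c("bin_i", "bin_j", "value")], chrom = chroms,
                bin_size_kb = bs, n_bins = header_nbins)
  } else {
    mat <- as.matrix(utils::read.table(text = lines, header = FALSE))
    dimnames(mat) <- NULL
    if (any(mat < 0)) stop("negative contact values are not allowed")
    contact_map(mat, chrom = if (is.null(chrom)) "chr" else chrom,
                bin_size_kb = bs)
  }
}

#' Write a binned contact map
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @param format `"coo"` (sparse triples, the default) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("coo", "dense")) {
  stopifnot(inherits(map, "binned_contact_map"))
  format <- match.arg(format)
  header <- sprintf("# contact map bin_size_kb=%g n_bins=%d",
                    map$bin_size_kb, map$n_bins)
  if (format == "coo") {
    tm <- methods::as(map$mat, "TsparseMatrix")
    df <- data.frame(chrom = map$chrom, bin_i = tm@i, bin_j = tm@j,
                     value = format(tm@x, digits = 17, trim = TRUE))
    df <- df[order(df$bin_i, df$bin_j), ]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(c("chrom", "bin_i", "bin_j", "value"),
                     collapse = "\t"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    dense <- as.matrix(map$mat)
    dense <- dense + t(dense) - diag(diag(dense))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(dense, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write fit results as a flat TSV table
#'
#' One row per fit: model id, parameter estimates, standard errors,
#' `R^2`, weighted SSR, helix-turn length and convergence metadata (the
#' layout of [compare_fits()]).
#'
#' @param fits A `chromatin_fit`, a list of them, or a ready
#'   `data.frame` (e.g. a [fit_virtual_profiles()] table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  tab <- if (is.data.frame(fits)) {
    fits
  } else if (inherits(fits, "chromatin_fit")) {
    as.data.frame(fits)
  } else {
    compare_fits(fits)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize one fit result as JSON
#'
#' @param fit A `chromatin_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "chromatin_fit"))
  payload <- list(
    model_id = fit$model_id,
    params = as.list(fit$params),
    stderr = as.list(fit$stderr),
    fixed = as.list(fit$fixed),
    r_squared = fit$r_squared,
    ssr = fit$ssr,
    n_obs = fit$n_obs,
    converged = fit$converged,
    n_starts = fit$n_starts,
    sh_kb = fit$sh_kb
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
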