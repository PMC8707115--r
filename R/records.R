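#' Column schema of a cytogenetic record table
#'
#' A record table has one row per published chromosome count, with columns:
#' \describe{
#'   \item{taxon}{Genus + epithet; morphospecies allowed ("sp.", "sp.1");
#'     subspecies as a third name part.}
#'   \item{diploid_number, haploid_number}{2n and/or n; at least one present.}
#'   \item{genome_size_1C}{Haploid genome size in pg, if estimated.}
#'   \item{locality, country}{Free-text provenance.}
#'   \item{karyotype}{Karyotype formula string, see [parse_formula()].}
#'   \item{karyotype_alt}{A second formula reported in the same source cell
#'     (kept verbatim when a compilation lists population variants).}
#'   \item{band_C, band_PC, band_IN, band_SA, band_LA}{Heterochromatin
#'     C-band position codes: "+" (positive block), "-" (negative), NA when
#'     the source left the cell blank (unknown). Positions: centromeric,
#'     pericentromeric, interstitial, short arm, long arm.}
#'   \item{source}{Free-text reference tag(s).}
#'   \item{is_new_report}{TRUE for counts first reported in the focal study.}
#' }
#' @name record_schema
#' @keywords internal
NULL

RECORD_COLUMNS <- c("taxon", "diploid_number", "haploid_number",
                    "genome_size_1C", "locality", "country", "karyotype",
                    "karyotype_alt", "band_C", "band_PC", "band_IN",
                    "band_SA", "band_LA", "source", "is_new_report")
BAND_COLUMNS <- c("band_C", "band_PC", "band_IN", "band_SA", "band_LA")

#' Genus synonym map used by taxon-name normalisation
#'
#' Compilations occasionally carry variant genus spellings; the map sends
#' each variant to the accepted spelling (e.g. "Serycomyrmex" to
#' "Sericomyrmex").
#'
#' @return Named character vector: names are variant spellings, values the
#'   accepted ones.
#' @export
attina_synonyms <- function() {
  c(Serycomyrmex = "Sericomyrmex", Myrmicocripta = "Myrmicocrypta")
}

#' Normalise a taxon name
#'
#' Strips markup (asterisks), collapses internal whitespace, capitalises the
#' genus, lower-cases the epithet(s), and applies the genus synonym map.
#'
#' @param x Character vector of taxon names.
#' @param synonyms Genus synonym map, see [attina_synonyms()].
#' @return Character vector of normalised names.
#' @examples
#' normalize_taxon("  *Serycomyrmex   parvulus* ")
#' @export
normalize_taxon <- function(x, synonyms = attina_synonyms()) {
  x <- gsub("*", "", x, fixed = TRUE)
  x <- gsub("_", " ", x, fixed = TRUE)  # phylo convention: underscore = space
  x <- gsub("\\s+", " ", trimws(x))
  vapply(x, function(name) {
    if (!nzchar(name)) return(name)
    parts <- strsplit(name, " ", fixed = TRUE)[[1L]]
    genus <- paste0(toupper(substring(parts[1L], 1, 1)),
                    tolower(substring(parts[1L], 2)))
    if (genus %in% names(synonyms)) genus <- synonyms[[genus]]
    rest <- if (length(parts) > 1L) tolower(parts[-1L]) else character(0)
    paste(c(genus, rest), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a record a morphospecies (not identified to species level)?
#'
#' Matches epithets of the form "sp." optionally suffixed with a number
#' ("sp.1", "sp.2").
#'
#' @param taxon Character vector of (normalised) taxon names.
#' @return Logical vector.
#' @export
is_morphospecies <- function(taxon) {
  epithet <- vapply(strsplit(taxon, " ", fixed = TRUE),
                    function(p) if (length(p) > 1L) p[2L] else "", character(1))
  grepl("^sp\\.?[0-9]*$", epithet)
}

#' Read a cytogenetic record table (TSV)
#'
#' Reads a UTF-8 tab-separated table following the [record_schema] (a
#' trailing parenthesised variant in the \code{karyotype} cell is split off
#' into \code{karyotype_alt}), normalises taxon names, derives the genus,
#' and checks the record invariants: at least one of 2n/n present, 2n = 2 n
#' when both are, genome sizes positive.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class \code{cytogenetic_records} with the schema
#'   columns plus \code{genus}.
#' @export
read_attina_records <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""),
                         fileEncoding = "UTF-8", comment.char = "")
  as_records(x)
}

#' Validate a data frame of cytogenetic records
#'
#' @param x A data frame with at least \code{taxon} and one of
#'   \code{diploid_number}/\code{haploid_number}; missing schema columns are
#'   added as NA.
#' @return A \code{cytogenetic_records} data frame.
#' @export
as_records <- function(x) {
  if (!is.data.frame(x) || nrow(x) == 0L || !"taxon" %in% names(x)) {
    stop("records must be a non-empty data frame with a 'taxon' column",
         call. = FALSE)
  }
  for (col in setdiff(RECORD_COLUMNS, names(x))) x[[col]] <- NA
  # split a trailing parenthesised variant formula kept verbatim in sources
  has_alt <- !is.na(x$karyotype) & grepl("\\(", x$karyotype) &
    is.na(x$karyotype_alt)
  if (any(has_alt)) {
    m <- regmatches(x$karyotype[has_alt],
                    regexec("^(.*?)\\s*\\((.*)\\)\\s*$", x$karyotype[has_alt]))
    x$karyotype_alt[has_alt] <- vapply(m, `[`, character(1), 3L)
    x$karyotype[has_alt] <- vapply(m, `[`, character(1), 2L)
  }
  x$taxon <- normalize_taxon(x$taxon)
  x$genus <- vapply(strsplit(x$taxon, " ", fixed = TRUE), `[`, character(1), 1L)
  for (col in c("diploid_number", "haploid_number", "genome_size_1C")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x$is_new_report <- !is.na(x$is_new_report) & as.logical(x$is_new_report)
  if (any(is.na(x$diploid_number) & is.na(x$haploid_number))) {
    stop("every record needs a diploid and/or haploid chromosome number",
         call. = FALSE)
  }
  both <- !is.na(x$diploid_number) & !is.na(x$haploid_number)
  if (any(x$diploid_number[both] != 2 * x$haploid_number[both])) {
    bad <- x$taxon[both][x$diploid_number[both] != 2 * x$haploid_number[both]]
    stop("2n != 2*n for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(x$genome_size_1C) & x$genome_size_1C <= 0)) {
    stop("genome sizes must be positive", call. = FALSE)
  }
  class(x) <- unique(c("cytogenetic_records", class(x)))
  x
}

#' Haploid chromosome number of each record
#'
#' Uses n directly when recorded, otherwise 2n / 2.
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @return Numeric vector, one value per record.
#' @export
record_haploid <- function(records) {
  ifelse(!is.na(records$haploid_number), records$haploid_number,
         records$diploid_number / 2)
}

#' Check a karyotype formula against the recorded chromosome count
#'
#' Compilations mix diploid and haploid formula conventions across sources,
#' so the status of each record is reported rather than raised: the formula
#' counts may sum to 2n (\code{diploid_consistent}), to n
#' (\code{haploid_consistent}), to neither (\code{inconsistent}), or the
#' formula may be absent (\code{no_formula}).
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @return Character vector of statuses, one per record.
#' @export
validate_records <- function(records) {
  records <- as_records(records)
  vapply(seq_len(nrow(records)), function(i) {
    kar <- records$karyotype[i]
    if (is.na(kar) || !nzchar(trimws(kar))) return("no_formula")
    total <- sum(parse_formula(kar))
    n2 <- records$diploid_number[i]
    if (is.na(n2)) n2 <- 2 * records$haploid_number[i]
    if (total == n2) "diploid_consistent"
    else if (total == n2 / 2) "haploid_consistent"
    else "inconsistent"
  }, character(1))
}

#' Summary statistics of a cytogenetic record compilation
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @return A list of class \code{record_summary}:
#' \describe{
#'   \item{record_count}{Number of rows (records, not taxa).}
#'   \item{distinct_taxon_karyotype_count}{Distinct (taxon, 2n-or-n) pairs.}
#'   \item{unidentified_count}{Records whose taxon is a morphospecies.}
#'   \item{taxa_with_gs_count}{Distinct taxon names carrying a genome size
#'     (records of one taxon from several populations count once).}
#'   \item{min_haploid, max_haploid}{Range of haploid numbers over records.}
#'   \item{mean_gs, sd_gs}{Mean and sample SD of the record-level genome
#'     sizes (each non-missing cell once, no deduplication by taxon).}
#'   \item{haploid_frequency}{Table of records per haploid number.}
#'   \item{genus_haploid}{Per genus, the sorted set of haploid numbers.}
#' }
#' @export
summarize_records <- function(records) {
  records <- as_records(records)
  n <- record_haploid(records)
  gs <- records$genome_size_1C
  structure(list(
    record_count = nrow(records),
    distinct_taxon_karyotype_count =
      nrow(unique(data.frame(records$taxon, n))),
    unidentified_count = sum(is_morphospecies(records$taxon)),
    taxa_with_gs_count = length(unique(records$taxon[!is.na(gs)])),
    min_haploid = min(n),
    max_haploid = max(n),
    mean_gs = if (all(is.na(gs))) NA_real_ else mean(gs, na.rm = TRUE),
    sd_gs = if (sum(!is.na(gs)) < 2) NA_real_ else stats::sd(gs, na.rm = TRUE),
    haploid_frequency = table(n),
    genus_haploid = lapply(split(n, records$genus),
                           function(v) sort(unique(v)))
  ), class = "record_summary")
}

#' @export
print.record_summary <- function(x, ...) {
  cat("Cytogenetic record summary\n")
  cat(sprintf("  records: %d (%d distinct taxon-karyotype pairs, %d morphospecies)\n",
              x$record_count, x$distinct_taxon_karyotype_count,
              x$unidentified_count))
  cat(sprintf("  haploid number range: %g-%g\n", x$min_haploid, x$max_haploid))
  if (!is.na(x$mean_gs)) {
    cat(sprintf("  genome size: %d taxa, mean %.2f pg (sd %.2f)\n",
                x$taxa_with_gs_count, x$mean_gs, x$sd_gs))
  }
  invisible(x)
}

#' Count positive heterochromatin positions of each record
#'
#' Counts "+" codes among the five C-band positions (centromeric,
#' pericentromeric, interstitial, short arm, long arm). Blank (unknown)
#' positions are excluded; a record with no coded position at all yields NA.
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @return Integer vector (NA where no position is coded).
#' @export
band_richness <- function(records) {
  bands <- as.matrix(records[, BAND_COLUMNS, drop = FALSE])
  pos <- rowSums(bands == "+", na.rm = TRUE)
  none <- rowSums(!is.na(bands)) == 0L
  ifelse(none, NA_integer_, as.integer(pos))
}

#' Compare heterochromatin band richness below and above a haploid threshold
#'
#' Splits the records carrying both a chromosome number and a C-band pattern
#' at a haploid-number threshold and reports group sizes, mean band richness
#' and how many records show positive blocks beyond the centromere. This is
#' a descriptive comparison (no hypothesis test is attached).
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @param n_threshold Haploid-number cut (default 15): groups are
#'   n <= threshold and n > threshold.
#' @return A data frame with one row per group: \code{group}, \code{size},
#'   \code{mean_richness}, \code{n_beyond_centromere}.
#' @export
band_richness_by_threshold <- function(records, n_threshold = 15) {
  records <- as_records(records)
  rich <- band_richness(records)
  n <- record_haploid(records)
  keep <- !is.na(rich)
  grp <- factor(ifelse(n[keep] > n_threshold, "above", "at_or_below"),
                levels = c("at_or_below", "above"))
  beyond <- rowSums(as.matrix(records[keep, setdiff(BAND_COLUMNS, "band_C"),
                                      drop = FALSE]) == "+",
                    na.rm = TRUE) > 0
  out <- data.frame(
    group = sprintf(c("n <= %g", "n > %g"), n_threshold),
    size = as.integer(table(grp)),
    mean_richness = as.numeric(tapply(rich[keep], grp, mean)),
    n_beyond_centromere = as.integer(tapply(beyond, grp, sum))
  )
  out$mean_richness[out$size == 0L] <- NA_real_
  out$n_beyond_centromere[out$size == 0L] <- NA_integer_
  out
}

#' Records with exceptionally large genome sizes
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @param threshold Flag records with 1C genome size >= this value in pg
#'   (default 0.50).
#' @return The flagged records, sorted by genome size descending.
#' @export
gs_exceptions <- function(records, threshold = 0.50) {
  records <- as_records(records)
  hit <- !is.na(records$genome_size_1C) & records$genome_size_1C >= threshold
  out <- records[hit, , drop = FALSE]
  out[order(-out$genome_size_1C), , drop = FALSE]
}
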