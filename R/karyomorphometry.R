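#' Arm ratio of a chromosome
#'
#' The arm ratio r is the long-arm length divided by the short-arm length.
#' Orientation is normalised first (the larger of the two measurements is
#' taken as the long arm), so the result is always >= 1.
#'
#' @param long_arm,short_arm Arm lengths in micrometres; vectors are recycled
#'   as usual.
#' @return Numeric vector of ratios, all >= 1.
#' @examples
#' arm_ratio(4.90, 2.00) # 2.45
#' arm_ratio(1.20, 1.63) # orientation normalised: 1.358...
#' @export
arm_ratio <- function(long_arm, short_arm) {
  if (any(!is.finite(long_arm)) || any(!is.finite(short_arm)) ||
      any(long_arm <= 0) || any(short_arm <= 0)) {
    stop("arm lengths must be positive and finite", call. = FALSE)
  }
  pmax(long_arm, short_arm) / pmin(long_arm, short_arm)
}

#' Arm-ratio thresholds for morphology classification
#'
#' Upper bounds of the arm-ratio intervals assigned to the metacentric,
#' submetacentric and subtelocentric classes; anything above the last bound
#' is telocentric. Defaults are the cutpoints m <= 1.5 < sm <= 3.0 <
#' st <= 7.0 < t (see the methods vignette for why this convention, rather
#' than a 1.7 metacentric bound, is used here).
#'
#' @param m,sm,st Upper bounds (inclusive) for the m, sm and st classes.
#' @return Named numeric vector of increasing thresholds.
#' @export
levan_thresholds <- function(m = 1.5, sm = 3.0, st = 7.0) {
  th <- c(m = m, sm = sm, st = st)
  if (any(!is.finite(th)) || is.unsorted(th, strictly = TRUE) || th[1] <= 1) {
    stop("thresholds must be finite, > 1 and strictly increasing", call. = FALSE)
  }
  th
}

#' Classify chromosome morphology from the arm ratio
#'
#' Assigns each arm ratio to one of the centromere-position classes of
#' Levan's nomenclature: metacentric (m), submetacentric (sm),
#' subtelocentric (st) or telocentric (t). Class intervals are closed on
#' their upper bound: r equal to a threshold belongs to the smaller class.
#'
#' @param r Numeric vector of arm ratios, all >= 1.
#' @param thresholds Class bounds, see [levan_thresholds()].
#' @return Character vector with values in \code{c("m","sm","st","t")}.
#' @examples
#' classify_levan(c(1.19, 1.70, 2.28, 4.5, 8))
#' @export
classify_levan <- function(r, thresholds = levan_thresholds()) {
  if (any(!is.finite(r))) stop("arm ratios must be finite", call. = FALSE)
  if (any(r < 1)) {
    stop("arm ratio < 1: orientation must be normalised (see arm_ratio)",
         call. = FALSE)
  }
  cls <- rep("t", length(r))
  cls[r <= thresholds[["st"]]] <- "st"
  cls[r <= thresholds[["sm"]]] <- "sm"
  cls[r <= thresholds[["m"]]] <- "m"
  cls
}

#' Relative length of a chromosome within a spread
#'
#' The percentage contribution of one chromosome's total length to the
#' summed total length of all chromosomes in the same metaphase:
#' TL_i * 100 / sum(TL). Over one spread the relative lengths sum to 100.
#'
#' @param tl_i Total length(s) of the chromosome(s) of interest (um).
#' @param tl_all Total lengths of all chromosomes in the spread; defaults to
#'   \code{tl_i} so that \code{relative_length(tl)} converts a whole spread.
#' @return Numeric vector of percentages.
#' @examples
#' relative_length(c(2, 2, 2, 2)) # 25 25 25 25
#' @export
relative_length <- function(tl_i, tl_all = tl_i) {
  if (length(tl_all) == 0L || any(!is.finite(tl_all)) || any(tl_all <= 0) ||
      any(!is.finite(tl_i)) || any(tl_i <= 0)) {
    stop("total lengths must be positive and finite", call. = FALSE)
  }
  tl_i * 100 / sum(tl_all)
}

#' Validate a table of per-metaphase arm measurements
#'
#' A spread table has one row per measured chromosome with columns
#' \code{spread_id}, \code{chromosome_index}, \code{long_um} and
#' \code{short_um}. Arm orientation is normalised on construction so that
#' \code{long_um >= short_um}.
#'
#' @param x A data frame with the four columns above.
#' @return The validated data frame (orientation normalised), with class
#'   \code{spread_table} prepended.
#' @export
as_spreads <- function(x) {
  required <- c("spread_id", "chromosome_index", "long_um", "short_um")
  if (!is.data.frame(x) || !all(required %in% names(x))) {
    stop("spread table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("spread table is empty", call. = FALSE)
  if (any(!is.finite(x$long_um)) || any(!is.finite(x$short_um)) ||
      any(x$long_um <= 0) || any(x$short_um <= 0)) {
    stop("arm measurements must be positive and finite", call. = FALSE)
  }
  long <- pmax(x$long_um, x$short_um)
  short <- pmin(x$long_um, x$short_um)
  x$long_um <- long
  x$short_um <- short
  x$spread_id <- as.character(x$spread_id)
  class(x) <- unique(c("spread_table", class(x)))
  x
}

#' Read a spread measurement table from CSV/TSV
#'
#' @param path File path; tab-separated if the extension is \code{.tsv},
#'   comma-separated otherwise. A header line is required and the decimal
#'   separator is the point.
#' @return A validated \code{spread_table}, see [as_spreads()].
#' @export
read_spreads <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  as_spreads(utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE))
}

# Per-spread size ranking and homologue pairing: chromosomes are sorted by
# total length descending (ties: long arm, then input order) and consecutive
# entries are paired. Returns the spread table with rank/pair columns.
rank_spread <- function(one, pair_homologues) {
  tl <- one$long_um + one$short_um
  ord <- order(-tl, -one$long_um, seq_len(nrow(one)))
  one <- one[ord, , drop = FALSE]
  one$TL <- tl[ord]
  one$rank <- seq_len(nrow(one))
  one$pair <- if (pair_homologues) (one$rank + 1L) %/% 2L else one$rank
  one$homologue <- if (pair_homologues) ((one$rank - 1L) %% 2L) + 1L else 1L
  one$r <- one$long_um / one$short_um
  one$RL <- relative_length(one$TL)
  one
}

#' Aggregate metaphase spreads into per-chromosome profiles
#'
#' Within each spread, chromosomes are ranked by total length descending and
#' (for diploid material) consecutive ranks are paired as homologues. Across
#' spreads, the mean and sample standard deviation of TL, L, S, RL and r are
#' computed per rank; the arm ratio and relative length are computed per
#' spread and then averaged. Morphology is classified from the mean arm
#' ratio. Profiles are returned in the conventional display order: pairs
#' grouped by morphology class (m before sm before st before t), within a
#' class by decreasing mean size, homologues consecutive.
#'
#' @param spreads A \code{spread_table} (see [as_spreads()]).
#' @param ploidy \code{"diploid"} (homologues paired; each spread must have
#'   an even chromosome count) or \code{"haploid"} (no pairing; male
#'   material).
#' @param thresholds Arm-ratio class bounds, see [levan_thresholds()].
#' @return A data frame of class \code{chromosome_profiles} with one row per
#'   chromosome: \code{rank}, \code{pair}, \code{homologue}, mean and sd of
#'   \code{TL}, \code{L}, \code{S}, \code{RL}, \code{r}, and
#'   \code{morphology}. A single spread yields standard deviations of 0.
#' @export
aggregate_spreads <- function(spreads, ploidy = c("diploid", "haploid"),
                              thresholds = levan_thresholds()) {
  spreads <- as_spreads(spreads)
  ploidy <- match.arg(ploidy)
  parts <- split(spreads, spreads$spread_id)
  counts <- vapply(parts, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    bad <- paste(sprintf("%s (%d)", names(counts), counts), collapse = ", ")
    stop("inconsistent chromosome counts across spreads: ", bad, call. = FALSE)
  }
  n_chr <- counts[[1L]]
  if (ploidy == "diploid" && n_chr %% 2L != 0L) {
    stop("odd chromosome count (", n_chr, ") with ploidy = 'diploid'",
         call. = FALSE)
  }
  ranked <- lapply(parts, rank_spread, pair_homologues = ploidy == "diploid")

  stat <- function(var, fun) {
    mat <- vapply(ranked, function(s) s[[var]], numeric(n_chr))
    mat <- matrix(mat, nrow = n_chr)
    apply(mat, 1L, fun)
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  prof <- data.frame(
    rank = seq_len(n_chr),
    pair = ranked[[1L]]$pair,
    homologue = ranked[[1L]]$homologue,
    mean_TL = stat("TL", mean), sd_TL = stat("TL", sd0),
    mean_L = stat("long_um", mean), sd_L = stat("long_um", sd0),
    mean_S = stat("short_um", mean), sd_S = stat("short_um", sd0),
    mean_RL = stat("RL", mean), sd_RL = stat("RL", sd0),
    mean_r = stat("r", mean), sd_r = stat("r", sd0)
  )
  prof$morphology <- classify_levan(prof$mean_r, thresholds)

  # display order: class-grouped as in published karyomorphometric tables
  pair_size <- stats::ave(prof$mean_TL, prof$pair, FUN = mean)
  pair_r <- stats::ave(prof$mean_r, prof$pair, FUN = mean)
  class_order <- match(classify_levan(pair_r, thresholds), MORPHOLOGY_LABELS)
  ord <- order(class_order, -pair_size, prof$pair, prof$homologue)
  prof <- prof[ord, , drop = FALSE]
  prof$pair <- cumsum(prof$homologue == 1L)
  prof$rank <- seq_len(n_chr)
  rownames(prof) <- NULL
  attr(prof, "ploidy") <- ploidy
  attr(prof, "n_spreads") <- length(ranked)
  class(prof) <- c("chromosome_profiles", class(prof))
  prof
}

#' Summarise a karyotype from chromosome profiles
#'
#' Derives the chromosome number, karyotype formula (counts per morphology
#' class), fundamental number (arm count) and karyotype length (sum of mean
#' total lengths, um) from an aggregated profile table. When the underlying
#' spreads are supplied, heteromorphic homologue pairs are flagged via
#' [detect_heteromorphism()].
#'
#' @param profiles A \code{chromosome_profiles} data frame from
#'   [aggregate_spreads()] (or a data frame with at least \code{mean_TL} and
#'   \code{morphology}).
#' @param ploidy \code{"diploid"} or \code{"haploid"}; defaults to the value
#'   recorded on \code{profiles}, else diploid.
#' @param spreads Optional \code{spread_table} used to screen homologue
#'   pairs for heteromorphism.
#' @param ... Passed on to [detect_heteromorphism()].
#' @return An object of class \code{karyotype_summary}: a list with
#'   \code{chromosome_number} (2n, or n for haploid material),
#'   \code{ploidy}, \code{formula}, \code{fundamental_number},
#'   \code{karyotype_length}, \code{profiles} and \code{heteromorphic_pairs}.
#' @export
summarize_karyotype <- function(profiles, ploidy = NULL, spreads = NULL, ...) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L ||
      !all(c("mean_TL", "morphology") %in% names(profiles))) {
    stop("profiles must be a non-empty data frame with mean_TL and morphology",
         call. = FALSE)
  }
  if (is.null(ploidy)) ploidy <- attr(profiles, "ploidy")
  if (is.null(ploidy)) ploidy <- "diploid"
  counts <- table(factor(profiles$morphology, levels = MORPHOLOGY_LABELS))
  formula <- as_karyotype_formula(stats::setNames(as.integer(counts),
                                                  names(counts)))
  het <- if (!is.null(spreads)) detect_heteromorphism(spreads, ...) else NULL
  het_pairs <- if (is.null(het)) integer(0) else het$pair[het$flagged]
  structure(list(
    chromosome_number = nrow(profiles),
    ploidy = ploidy,
    formula = formula,
    fundamental_number = fundamental_number(formula),
    karyotype_length = sum(profiles$mean_TL),
    profiles = profiles,
    heteromorphic_pairs = het_pairs,
    heteromorphism = het
  ), class = "karyotype_summary")
}

#' @export
print.karyotype_summary <- function(x, digits = 2, ...) {
  label <- if (x$ploidy == "diploid") "2n" else "n"
  cat(sprintf("Karyotype summary (%s material)\n", x$ploidy))
  cat(sprintf("  %s = %d, 2K = %s, FN = %d, KL = %s um\n", label,
              x$chromosome_number, format_formula(x$formula),
              x$fundamental_number, round(x$karyotype_length, digits)))
  if (length(x$heteromorphic_pairs)) {
    cat("  heteromorphic pair(s): ",
        paste(x$heteromorphic_pairs, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Screen homologue pairs for heteromorphism
#'
#' A homologue pair is flagged as putatively heteromorphic when, across
#' spreads, the two homologues fall in different morphology classes in at
#' least \code{class_frac} of spreads, or when their mean total lengths
#' differ by more than the factor \code{tl_ratio}. Defaults are chosen to
#' flag a persistent class difference (as in a published submetacentric
#' pair-15 polymorphism) without flagging measurement noise.
#'
#' @param spreads A \code{spread_table} of diploid material.
#' @param pair_index Optional integer vector restricting the screen to the
#'   given pairs (size-rank pairing, 1 = largest); default all pairs.
#' @param class_frac Fraction of spreads with differing homologue classes
#'   needed to flag a pair (default 0.5).
#' @param tl_ratio Mean-TL ratio (larger/smaller homologue) above which a
#'   pair is flagged (default 1.25).
#' @param thresholds Arm-ratio class bounds, see [levan_thresholds()].
#' @return A data frame with one row per screened pair: \code{pair},
#'   \code{frac_class_diff}, \code{tl_ratio}, \code{flagged}, plus the
#'   per-spread evidence as attribute \code{"evidence"}.
#' @export
detect_heteromorphism <- function(spreads, pair_index = NULL,
                                  class_frac = 0.5, tl_ratio = 1.25,
                                  thresholds = levan_thresholds()) {
  spreads <- as_spreads(spreads)
  ranked <- lapply(split(spreads, spreads$spread_id), rank_spread,
                   pair_homologues = TRUE)
  n_chr <- nrow(ranked[[1L]])
  if (n_chr %% 2L != 0L) {
    stop("heteromorphism screening needs an even (diploid) chromosome count",
         call. = FALSE)
  }
  n_pairs <- n_chr %/% 2L
  if (is.null(pair_index)) pair_index <- seq_len(n_pairs)
  if (any(pair_index < 1L | pair_index > n_pairs)) {
    stop("pair_index out of range 1..", n_pairs, call. = FALSE)
  }
  evidence <- do.call(rbind, lapply(names(ranked), function(id) {
    s <- ranked[[id]]
    a <- s[s$homologue == 1L, ]
    b <- s[s$homologue == 2L, ]
    data.frame(spread_id = id, pair = a$pair,
               class_1 = classify_levan(a$r, thresholds),
               class_2 = classify_levan(b$r, thresholds),
               TL_1 = a$TL, TL_2 = b$TL)
  }))
  out <- do.call(rbind, lapply(pair_index, function(k) {
    ev <- evidence[evidence$pair == k, ]
    frac <- mean(ev$class_1 != ev$class_2)
    m1 <- mean(ev$TL_1); m2 <- mean(ev$TL_2)
    ratio <- max(m1, m2) / min(m1, m2)
    data.frame(pair = k, frac_class_diff = frac, tl_ratio = ratio,
               flagged = frac >= class_frac || ratio > tl_ratio)
  }))
  rownames(out) <- NULL
  attr(out, "evidence") <- evidence[evidence$pair %in% pair_index, ]
  out
}

#' Format chromosome profiles as a publication-style table
#'
#' Renders a profile table in the layout of published karyomorphometric
#' tables: one row per chromosome labelled \code{"k"} / \code{"(k)"} for the
#' two homologues of pair k, columns TL, L, S, RL and r as
#' \code{"mean +/- sd"}, a Classification column, and a final KL row.
#' Values are rounded half-to-even.
#'
#' @param profiles A \code{chromosome_profiles} data frame.
#' @param digits Decimal places for table-facing output (default 2).
#' @return A character data frame ready for writing with
#'   [utils::write.table()].
#' @export
format_profile_table <- function(profiles, digits = 2) {
  fmt <- function(m, s) sprintf("%.*f ± %.*f", digits, round(m, digits),
                                digits, round(s, digits))
  label <- ifelse(profiles$homologue == 2L, sprintf("(%d)", profiles$pair),
                  sprintf("%d", profiles$pair))
  full <- c(m = "Metacentric", sm = "Submetacentric",
            st = "Subtelocentric", t = "Telocentric")
  out <- data.frame(
    Chromosome = label,
    TL = fmt(profiles$mean_TL, profiles$sd_TL),
    L = fmt(profiles$mean_L, profiles$sd_L),
    S = fmt(profiles$mean_S, profiles$sd_S),
    RL = fmt(profiles$mean_RL, profiles$sd_RL),
    r = fmt(profiles$mean_r, profiles$sd_r),
    Classification = unname(full[profiles$morphology]),
    stringsAsFactors = FALSE
  )
  rbind(out, data.frame(
    Chromosome = "KL",
    TL = sprintf("%.*f", digits, round(sum(profiles$mean_TL), digits)),
    L = "", S = "", RL = "", r = "", Classification = ""
  ))
}
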