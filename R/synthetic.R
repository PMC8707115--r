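#' Define a true karyotype for spread simulation
#'
#' The ground truth for simulating metaphase spreads: one row per chromosome
#' pair with its true total length (um) and true arm ratio.
#'
#' @param tl Numeric vector of true total lengths (um), one per pair.
#' @param r Numeric vector of true arm ratios, all >= 1.
#' @param ploidy \code{"diploid"} (each pair contributes two identical
#'   homologues per spread) or \code{"haploid"}.
#' @return A list of class \code{true_karyotype}.
#' @export
true_karyotype <- function(tl, r, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (length(tl) == 0L || length(tl) != length(r) ||
      any(!is.finite(tl)) || any(tl <= 0) || any(!is.finite(r)) || any(r < 1)) {
    stop("true karyotype needs positive lengths and ratios >= 1, same length",
         call. = FALSE)
  }
  structure(list(tl = tl, r = r, ploidy = ploidy), class = "true_karyotype")
}

#' Simulate noisy metaphase spreads around a true karyotype
#'
#' Emulates the two dominant sources of measurement variation in
#' karyomorphometry: chromosome condensation differs between metaphases
#' (all chromosomes of one spread scale together) and individual arm
#' measurements carry independent error. Per spread j a condensation factor
#' c_j is drawn log-normal with median 1 and log-SD \code{condensation_sd};
#' each arm is then multiplied by c_j * (1 + e) with
#' e ~ Normal(0, arm_noise_sd). For diploid truth each pair contributes two
#' homologues.
#'
#' @param truth A \code{true_karyotype}.
#' @param n_spreads Number of spreads to simulate (>= 1).
#' @param condensation_sd Log-SD of the per-spread condensation factor
#'   (default 0.10, i.e. ~10% spread-to-spread scaling).
#' @param arm_noise_sd SD of the relative per-arm measurement error
#'   (default 0.02).
#' @param seed Integer seed (required; identical seeds give identical
#'   output).
#' @return A \code{spread_table} (see [as_spreads()]).
#' @export
simulate_spreads <- function(truth, n_spreads, condensation_sd = 0.10,
                             arm_noise_sd = 0.02, seed) {
  stopifnot(inherits(truth, "true_karyotype"), n_spreads >= 1,
            condensation_sd >= 0, arm_noise_sd >= 0)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  copies <- if (truth$ploidy == "diploid") 2L else 1L
  long_true <- rep(truth$tl * truth$r / (1 + truth$r), each = copies)
  short_true <- rep(truth$tl / (1 + truth$r), each = copies)
  n_chr <- length(long_true)
  out <- do.call(rbind, lapply(seq_len(n_spreads), function(j) {
    cj <- exp(stats::rnorm(1, 0, condensation_sd))
    noisy <- function(x) {
      pmax(x * cj * (1 + stats::rnorm(n_chr, 0, arm_noise_sd)), 1e-6)
    }
    data.frame(spread_id = sprintf("S%03d", j),
               chromosome_index = seq_len(n_chr),
               long_um = noisy(long_true),
               short_um = noisy(short_true))
  }))
  as_spreads(out)
}

#' Define a chromosome-number / genome-size evolution model
#'
#' A continuous-time fission/fusion model of haploid chromosome-number
#' change along a time-calibrated tree, with Brownian genome-size
#' evolution. Fissions (n to n+1) occur at \code{fission_rate} and fusions
#' (n to n-1) at \code{fusion_rate} events per Myr; the chain reflects at
#' \code{n_min} (no fusion below it) and, when \code{n_cap} is set, cannot
#' fission above the cap - an explicit embodiment of an upper limit to
#' chromosome number. Genome size evolves as Brownian motion with rate
#' \code{gs_sigma} (pg per sqrt(Myr)) around the root value \code{gs_root};
#' optionally each fission adds \code{gs_fission_jump} pg, emulating
#' heterochromatin amplification at new centromere ends.
#'
#' @param fission_rate,fusion_rate Event rates per Myr (>= 0).
#' @param n_min Lower reflecting bound (default 1).
#' @param n_cap Optional upper cap (NULL = unbounded).
#' @param gs_root Root 1C genome size in pg (default 0.38).
#' @param gs_sigma Brownian rate in pg/sqrt(Myr) (default 0.02).
#' @param gs_fission_jump Optional pg added to genome size per fission.
#' @return A list of class \code{evol_model}.
#' @export
evol_model <- function(fission_rate = 0.05, fusion_rate = 0.05, n_min = 1L,
                       n_cap = NULL, gs_root = 0.38, gs_sigma = 0.02,
                       gs_fission_jump = NULL) {
  stopifnot(fission_rate >= 0, fusion_rate >= 0, n_min >= 1,
            is.null(n_cap) || n_cap >= n_min, gs_root > 0, gs_sigma >= 0,
            is.null(gs_fission_jump) || gs_fission_jump >= 0)
  structure(list(fission_rate = fission_rate, fusion_rate = fusion_rate,
                 n_min = as.integer(n_min),
                 n_cap = if (is.null(n_cap)) NULL else as.integer(n_cap),
                 gs_root = gs_root, gs_sigma = gs_sigma,
                 gs_fission_jump = gs_fission_jump),
            class = "evol_model")
}

# simulate the bounded birth/death walk along one branch; returns the end
# state and the event times (relative to the branch start)
walk_branch <- function(n0, len, model) {
  n <- n0
  t <- 0
  times <- numeric(0); types <- character(0); states <- integer(0)
  repeat {
    up <- if (is.null(model$n_cap) || n < model$n_cap) model$fission_rate else 0
    down <- if (n > model$n_min) model$fusion_rate else 0
    total <- up + down
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t >= len) break
    fission <- stats::runif(1) < up / total
    n <- n + if (fission) 1L else -1L
    times <- c(times, t)
    types <- c(types, if (fission) "fission" else "fusion")
    states <- c(states, n)
  }
  list(n = n, times = times, types = types, states = states)
}

#' Simulate fission/fusion chromosome-number evolution on a tree
#'
#' Runs the continuous-time chain of [evol_model()] along every branch of a
#' time-calibrated tree, recording each event.
#'
#' @param tree A \code{phylo} with branch lengths in Myr.
#' @param model An \code{evol_model}.
#' @param root_n Haploid number at the root (>= \code{n_min}).
#' @param seed Integer seed (required).
#' @return A list of class \code{karyo_evolution}: \code{tip_n} (named
#'   vector over tips), \code{node_n} (states at all nodes), and
#'   \code{events} (data frame with \code{edge}, \code{parent},
#'   \code{child}, \code{time} along the branch, \code{type},
#'   \code{state_after}).
#' @export
simulate_chromosome_evolution <- function(tree, model, root_n, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "evol_model"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (root_n < model$n_min) stop("root_n below n_min", call. = FALSE)
  if (!is.null(model$n_cap) && root_n > model$n_cap) {
    stop("root_n above n_cap", call. = FALSE)
  }
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  state <- rep(NA_integer_, n_tip + tree$Nnode)
  state[root] <- as.integer(root_n)
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  events <- list()
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    res <- walk_branch(state[p], ord$edge.length[i], model)
    state[ch] <- res$n
    if (length(res$times)) {
      events[[length(events) + 1L]] <- data.frame(
        edge = i, parent = p, child = ch, time = res$times,
        type = res$types, state_after = res$states)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(edge = integer(0), parent = integer(0), child = integer(0),
               time = numeric(0), type = character(0),
               state_after = integer(0))
  structure(list(
    tip_n = stats::setNames(state[seq_len(n_tip)], tree$tip.label),
    node_n = state,
    events = events,
    tree = tree, model = model, root_n = as.integer(root_n)
  ), class = "karyo_evolution")
}

#' Simulate Brownian genome-size evolution on a tree
#'
#' Genome size changes along each branch by a Normal(0,
#' gs_sigma^2 * branch length) increment, floored at a small positive
#' value. When a fission event log from [simulate_chromosome_evolution()]
#' is supplied and the model sets \code{gs_fission_jump}, each fission on a
#' branch adds that jump - coupling chromosome-number gain to
#' repetitive-DNA-driven genome growth.
#'
#' @param tree A \code{phylo} with branch lengths in Myr.
#' @param model An \code{evol_model}.
#' @param seed Integer seed (required).
#' @param events Optional event log (the \code{events} element of a
#'   \code{karyo_evolution}, or such an object itself).
#' @return Named numeric vector of tip genome sizes (pg).
#' @export
simulate_gs <- function(tree, model, seed, events = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "evol_model"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  set.seed(seed)
  if (inherits(events, "karyo_evolution")) events <- events$events
  n_tip <- length(tree$tip.label)
  gs <- rep(NA_real_, n_tip + tree$Nnode)
  gs[n_tip + 1L] <- model$gs_root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    delta <- stats::rnorm(1, 0, model$gs_sigma * sqrt(ord$edge.length[i]))
    jump <- 0
    if (!is.null(model$gs_fission_jump) && !is.null(events) && nrow(events)) {
      k <- sum(events$parent == p & events$child == ch &
                 events$type == "fission")
      jump <- k * model$gs_fission_jump
    }
    gs[ch] <- max(gs[p] + delta + jump, 1e-4)
  }
  stats::setNames(gs[seq_len(n_tip)], tree$tip.label)
}

#' Specification for a synthetic cytogenetic record table
#'
#' @param genera Named integer vector: records per genus.
#' @param n_values Named list (same names) of haploid numbers to sample
#'   from, one pool per genus.
#' @param gs_mean,gs_sd Genome-size sampling distribution (Normal truncated
#'   positive), pg. Defaults centred on 0.38 pg with moderate spread.
#' @param gs_frac Fraction of records carrying a genome size.
#' @param unidentified_frac Fraction of records labelled as morphospecies.
#' @param pattern_frac Fraction of records carrying a C-band pattern.
#' @return A list of class \code{synth_records_spec}.
#' @export
synth_records_spec <- function(genera, n_values, gs_mean = 0.38,
                               gs_sd = 0.05, gs_frac = 0.6,
                               unidentified_frac = 0.15,
                               pattern_frac = 0.5) {
  stopifnot(length(genera) > 0, !is.null(names(genera)),
            identical(sort(names(genera)), sort(names(n_values))),
            gs_mean > 0, gs_sd >= 0,
            gs_frac >= 0, gs_frac <= 1,
            unidentified_frac >= 0, unidentified_frac <= 1,
            pattern_frac >= 0, pattern_frac <= 1)
  structure(list(genera = genera, n_values = n_values, gs_mean = gs_mean,
                 gs_sd = gs_sd, gs_frac = gs_frac,
                 unidentified_frac = unidentified_frac,
                 pattern_frac = pattern_frac),
            class = "synth_records_spec")
}

#' Generate a synthetic cytogenetic record table with known ground truth
#'
#' Emits a record table following the [record_schema] together with a
#' ledger of the summary statistics a correct [summarize_records()] must
#' recover exactly; the ledger is bookkept during generation, independently
#' of the summary code.
#'
#' @param spec A \code{synth_records_spec}.
#' @param seed Integer seed (required; identical seeds give identical
#'   tables).
#' @return A list with \code{records} (a \code{cytogenetic_records} data
#'   frame) and \code{truth} (list: \code{record_count},
#'   \code{unidentified_count}, \code{taxa_with_gs_count},
#'   \code{records_with_gs}, \code{mean_gs}, \code{min_haploid},
#'   \code{max_haploid}, \code{pattern_count}).
#' @export
make_fixture_tables <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_records_spec"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  rows <- list()
  truth <- list(record_count = 0L, unidentified_count = 0L,
                pattern_count = 0L, gs_values = numeric(0),
                gs_taxa = character(0), haploid = numeric(0))
  for (genus in names(spec$genera)) {
    k <- spec$genera[[genus]]
    pool <- spec$n_values[[genus]]
    n_unident <- round(k * spec$unidentified_frac)
    sp_counter <- 0L
    for (i in seq_len(k)) {
      unident <- i <= n_unident
      if (unident) {
        sp_counter <- sp_counter + 1L
        taxon <- sprintf("%s sp.%d", genus, sp_counter)
      } else {
        taxon <- sprintf("%s species%02d", genus, i)
      }
      n <- if (length(pool) == 1L) pool else sample(pool, 1L)
      has_gs <- stats::runif(1) < spec$gs_frac
      gs <- if (has_gs) {
        v <- stats::rnorm(1, spec$gs_mean, spec$gs_sd)
        while (v <= 0) v <- stats::rnorm(1, spec$gs_mean, spec$gs_sd)
        round(v, 2)
      } else NA_real_
      has_pattern <- stats::runif(1) < spec$pattern_frac
      bands <- if (has_pattern) {
        c("+", sample(c("+", "-"), 4L, replace = TRUE))
      } else rep(NA_character_, 5L)
      n_m <- 2L * sample.int(n, 1L)
      n_sm <- 2L * n - n_m
      formula <- format_formula(karyotype_formula(m = n_m, sm = n_sm))
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, diploid_number = 2 * n, haploid_number = n,
        genome_size_1C = gs, locality = NA_character_,
        country = NA_character_, karyotype = formula,
        karyotype_alt = NA_character_,
        band_C = bands[1L], band_PC = bands[2L], band_IN = bands[3L],
        band_SA = bands[4L], band_LA = bands[5L],
        source = "synthetic", is_new_report = FALSE,
        stringsAsFactors = FALSE)
      truth$record_count <- truth$record_count + 1L
      truth$unidentified_count <- truth$unidentified_count + as.integer(unident)
      truth$pattern_count <- truth$pattern_count + as.integer(has_pattern)
      if (has_gs) {
        truth$gs_values <- c(truth$gs_values, gs)
        truth$gs_taxa <- c(truth$gs_taxa, taxon)
      }
      truth$haploid <- c(truth$haploid, n)
    }
  }
  records <- as_records(do.call(rbind, rows))
  truth_out <- list(
    record_count = truth$record_count,
    unidentified_count = truth$unidentified_count,
    taxa_with_gs_count = length(unique(truth$gs_taxa)),
    records_with_gs = length(truth$gs_values),
    mean_gs = if (length(truth$gs_values)) mean(truth$gs_values) else NA_real_,
    min_haploid = min(truth$haploid),
    max_haploid = max(truth$haploid),
    pattern_count = truth$pattern_count
  )
  list(records = records, truth = truth_out)
}
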