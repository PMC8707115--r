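#' Read and validate a time-calibrated tree
#'
#' Reads a Newick tree (branch lengths in Myr required), checks that tip
#' labels are unique and that the tree is ultrametric: all root-to-tip path
#' lengths equal within a relative tolerance.
#'
#' @param path Newick file path.
#' @param tol Relative ultrametricity tolerance (default 1e-6 of tree depth).
#' @return An \code{ape} \code{phylo} object.
#' @export
read_timetree <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  validate_timetree(tree, tol)
}

#' @rdname read_timetree
#' @param tree A \code{phylo} object.
#' @export
validate_timetree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol * max(depths)) {
    stop("tree is not ultrametric within tolerance ", tol, call. = FALSE)
  }
  tree
}

#' Ages (Myr before present) of all nodes of an ultrametric tree
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @return Numeric vector over nodes 1..(Ntip + Nnode): tip ages ~0, root
#'   age = tree depth.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

#' Build a per-taxon trait table from cytogenetic records
#'
#' Reconciles multiple records per taxon into a single (haploid number,
#' genome size) pair: records flagged as new reports take precedence, then
#' table order; the genome size is the first non-missing value in that
#' order. Taxa whose records disagree on the haploid number are flagged.
#'
#' @param records A \code{cytogenetic_records} data frame.
#' @param prefer_new Give precedence to \code{is_new_report} records
#'   (default TRUE).
#' @return A data frame with columns \code{taxon}, \code{n}, \code{gs_pg},
#'   \code{n_conflict}.
#' @export
make_trait_table <- function(records, prefer_new = TRUE) {
  records <- as_records(records)
  n_all <- record_haploid(records)
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), records$taxon),
    function(idx) {
      if (prefer_new) idx <- idx[order(!records$is_new_report[idx])]
      ns <- n_all[idx]
      gs <- records$genome_size_1C[idx]
      data.frame(taxon = records$taxon[idx[1L]],
                 n = ns[1L],
                 gs_pg = if (any(!is.na(gs))) gs[!is.na(gs)][1L] else NA_real_,
                 n_conflict = length(unique(ns)) > 1L)
    }))
  rownames(out) <- NULL
  out
}

tip_key <- function(x) tolower(gsub("_", " ", x, fixed = TRUE))

#' Attach chromosome-number and genome-size traits to tree tips
#'
#' Matches trait-table taxa to tip labels exactly (case-insensitively, with
#' underscores treated as spaces) and optionally falls back to a
#' genus-level average for unmatched tips.
#'
#' @param tree A validated \code{phylo} (see [read_timetree()]).
#' @param traits A data frame with columns \code{taxon}, \code{n},
#'   \code{gs_pg} (see [make_trait_table()]).
#' @param genus_fallback If TRUE, a tip with no exact match but a single
#'   genus in the trait table takes the genus mean (default FALSE).
#' @return A list of class \code{annotated_tree}: \code{tree}, named
#'   vectors \code{n} and \code{gs} over tips (NA where unknown), and a
#'   \code{report} listing matched tips, unmatched tips and unused traits.
#' @export
attach_traits <- function(tree, traits, genus_fallback = FALSE) {
  tree <- validate_timetree(tree)
  if (!is.data.frame(traits) || nrow(traits) == 0L ||
      !all(c("taxon", "n") %in% names(traits))) {
    stop("traits must be a data frame with columns taxon, n (and gs_pg)",
         call. = FALSE)
  }
  if (is.null(traits$gs_pg)) traits$gs_pg <- NA_real_
  key <- tip_key(normalize_taxon(traits$taxon))
  if (anyDuplicated(key)) {
    stop("duplicate taxa in trait table: ",
         paste(unique(traits$taxon[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  tips <- tree$tip.label
  hit <- match(tip_key(tips), key)
  n <- stats::setNames(traits$n[hit], tips)
  gs <- stats::setNames(traits$gs_pg[hit], tips)
  fallback <- character(0)
  if (genus_fallback && any(is.na(hit))) {
    genus_of <- function(x) vapply(strsplit(x, " ", fixed = TRUE), `[`,
                                   character(1), 1L)
    trait_genus <- genus_of(key)
    for (i in which(is.na(hit))) {
      g <- genus_of(tip_key(tips[i]))
      in_genus <- trait_genus == g
      if (any(in_genus)) {
        n[i] <- mean(traits$n[in_genus], na.rm = TRUE)
        gs[i] <- mean(traits$gs_pg[in_genus], na.rm = TRUE)
        fallback <- c(fallback, tips[i])
      }
    }
  }
  if (all(is.na(n)) && all(is.na(gs))) {
    stop("no trait-table taxon matches any tip label", call. = FALSE)
  }
  structure(list(
    tree = tree, n = n, gs = gs,
    report = list(
      matched = tips[!is.na(hit)],
      genus_fallback = fallback,
      unmatched_tips = setdiff(tips[is.na(n) & is.na(gs)], fallback),
      unused_traits = traits$taxon[!key %in% tip_key(tips)]
    )
  ), class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("Annotated time tree: %d tips, %d with n, %d with genome size\n",
              length(x$tree$tip.label), sum(!is.na(x$n)), sum(!is.na(x$gs))))
  if (length(x$report$unmatched_tips)) {
    cat("  tips without traits: ", length(x$report$unmatched_tips), "\n")
  }
  invisible(x)
}

# For each node (tips included), counts of trait-bearing descendant tips
# equal / not equal to `value`. Postorder accumulation over the edge matrix.
clade_uniformity <- function(tree, trait, value) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  eq <- neq <- integer(n_node)
  has <- !is.na(trait)
  eq[seq_len(n_tip)] <- as.integer(has & trait == value)
  neq[seq_len(n_tip)] <- as.integer(has & trait != value)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]; ch <- edges[i, 2L]
    eq[p] <- eq[p] + eq[ch]
    neq[p] <- neq[p] + neq[ch]
  }
  list(eq = eq, neq = neq)
}

#' Maximal clades uniform for a given haploid number
#'
#' Finds every maximal monophyletic group in which all trait-bearing tips
#' share the given haploid number and at least one tip bears it. Tips
#' without a trait are neutral: they neither support nor break uniformity
#' (set \code{strict = TRUE} to require every tip of a clade to carry the
#' trait). Single tips count as (degenerate) clades; a polytomous
#' ancestor is one clade.
#'
#' @param at An \code{annotated_tree} from [attach_traits()].
#' @param n The haploid number of interest.
#' @param strict Require all tips of a clade to be trait-bearing.
#' @return A data frame sorted by crown age descending: \code{node} (ape
#'   node id), \code{n_tips} (tips in the clade), \code{n_trait_tips},
#'   \code{crown_age}, \code{stem_age} (NA at the root), and a list column
#'   \code{tips}.
#' @export
fixed_number_clades <- function(at, n, strict = FALSE) {
  stopifnot(inherits(at, "annotated_tree"))
  tree <- at$tree
  n_tip <- length(tree$tip.label)
  u <- clade_uniformity(tree, at$n, n)
  clade_size <- integer(n_tip + tree$Nnode)
  clade_size[seq_len(n_tip)] <- 1L
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    clade_size[edges[i, 1L]] <- clade_size[edges[i, 1L]] +
      clade_size[edges[i, 2L]]
  }
  uniform <- u$eq > 0L & u$neq == 0L
  if (strict) uniform <- uniform & (u$eq == clade_size)
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  maximal <- which(uniform & (is.na(parent) | !uniform[parent]))
  ages <- node_ages(tree)
  tip_sets <- lapply(maximal, function(nd) {
    if (nd <= n_tip) tree$tip.label[nd]
    else tree$tip.label[intersect(ape::prop.part(tree)[[nd - n_tip]],
                                  seq_len(n_tip))]
  })
  out <- data.frame(
    node = maximal,
    n_tips = clade_size[maximal],
    n_trait_tips = u$eq[maximal],
    crown_age = ages[maximal],
    stem_age = ifelse(is.na(parent[maximal]), NA_real_, ages[parent[maximal]])
  )
  out$tips <- tip_sets
  out <- out[order(-out$crown_age, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clade-level stasis summary over all observed haploid numbers
#'
#' For each haploid number present among the tips, reports the maximal
#' uniform clades (see [fixed_number_clades()]), how many mutually
#' independent such clades exist, and the span of their crown ages. Numbers
#' recurring in several old, independent clades indicate long-term
#' karyotype stasis.
#'
#' @param at An \code{annotated_tree} from [attach_traits()].
#' @param strict Passed to [fixed_number_clades()].
#' @return A list of class \code{stasis_summary}: \code{by_number} (a data
#'   frame with \code{n}, \code{independent_clade_count},
#'   \code{oldest_crown_age}, \code{total_trait_tips}), \code{clades} (the
#'   per-number clade tables), and \code{modal_n} (the most frequent
#'   haploid number(s) across trait-bearing tips).
#' @export
stasis_summary <- function(at, strict = FALSE) {
  stopifnot(inherits(at, "annotated_tree"))
  values <- sort(unique(at$n[!is.na(at$n)]))
  if (length(values) == 0L) stop("no tip carries a haploid number", call. = FALSE)
  clades <- lapply(values, function(v) fixed_number_clades(at, v, strict))
  names(clades) <- as.character(values)
  by_number <- data.frame(
    n = values,
    independent_clade_count = vapply(clades, nrow, integer(1)),
    oldest_crown_age = vapply(clades, function(cl)
      if (nrow(cl)) max(cl$crown_age) else NA_real_, numeric(1)),
    total_trait_tips = vapply(clades, function(cl)
      sum(cl$n_trait_tips), integer(1))
  )
  rownames(by_number) <- NULL
  freq <- table(at$n[!is.na(at$n)])
  structure(list(
    by_number = by_number,
    clades = clades,
    modal_n = as.numeric(names(freq)[freq == max(freq)])
  ), class = "stasis_summary")
}

#' @export
print.stasis_summary <- function(x, ...) {
  cat("Karyotype stasis summary (maximal uniform clades per haploid number)\n")
  print(x$by_number, row.names = FALSE)
  cat("modal haploid number(s): ", paste(x$modal_n, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tips departing from the central genome size
#'
#' Flags tips whose genome size lies outside [center / factor,
#' center * factor], the multiplicative band around the compilation mean.
#'
#' @param at An \code{annotated_tree} from [attach_traits()].
#' @param center Central 1C genome size in pg (default 0.38).
#' @param factor Multiplicative departure factor (default 1.3).
#' @return A data frame sorted by genome size descending: \code{tip},
#'   \code{gs_pg}, \code{direction} ("high"/"low"), \code{genus}.
#' @export
gs_departures_on_tree <- function(at, center = 0.38, factor = 1.3) {
  stopifnot(inherits(at, "annotated_tree"), center > 0, factor >= 1)
  gs <- at$gs[!is.na(at$gs)]
  if (length(gs) == 0L) stop("no tip carries a genome size", call. = FALSE)
  high <- gs > center * factor
  low <- gs < center / factor
  hit <- gs[high | low]
  out <- data.frame(
    tip = names(hit),
    gs_pg = unname(hit),
    direction = ifelse(hit > center, "high", "low"),
    genus = vapply(strsplit(gsub("_", " ", names(hit)), " ", fixed = TRUE),
                   `[`, character(1), 1L)
  )
  out <- out[order(-out$gs_pg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a Newick tree with trait annotations as bracket comments
#'
#' Appends \code{[&n=...,gs=...]} comments to tip labels so downstream
#' viewers that understand bracket comments can display the traits.
#'
#' @param at An \code{annotated_tree}.
#' @param path Output file path.
#' @return Invisibly, the Newick string written.
#' @export
write_annotated_newick <- function(at, path) {
  stopifnot(inherits(at, "annotated_tree"))
  tree <- at$tree
  nwk <- ape::write.tree(tree)
  for (i in seq_along(tree$tip.label)) {
    tag <- c(if (!is.na(at$n[i])) sprintf("n=%g", at$n[i]),
             if (!is.na(at$gs[i])) sprintf("gs=%g", at$gs[i]))
    if (length(tag)) {
      nwk <- sub(paste0(tree$tip.label[i], ":"),
                 sprintf("%s[&%s]:", tree$tip.label[i],
                         paste(tag, collapse = ",")),
                 nwk, fixed = TRUE)
    }
  }
  writeLines(nwk, path)
  invisible(nwk)
}
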