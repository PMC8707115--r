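# shared helpers for the test suite

# a small, well-separated diploid truth: sizes 20% apart, ratios well away
# from the class thresholds (1.5, 3, 7)
toy_truth <- function() {
  true_karyotype(tl = c(10, 8, 6.5, 5, 4),
                 r = c(1.2, 1.3, 2.0, 2.5, 4.0),
                 ploidy = "diploid")
}

toy_classes <- function() classify_levan(c(1.2, 1.3, 2.0, 2.5, 4.0))

# independent brute-force enumeration of maximal uniform clades: for every
# node (tips included) collect its tip set directly from the edge matrix by
# repeated expansion, test uniformity, then drop nodes whose parent is also
# uniform
brute_force_clades <- function(tree, trait, value) {
  n_tip <- length(tree$tip.label)
  all_nodes <- seq_len(n_tip + tree$Nnode)
  tips_of <- function(node) {
    frontier <- node
    tips <- integer(0)
    while (length(frontier)) {
      nd <- frontier[1]; frontier <- frontier[-1]
      if (nd <= n_tip) tips <- c(tips, nd)
      else frontier <- c(frontier, tree$edge[tree$edge[, 1] == nd, 2])
    }
    sort(tips)
  }
  uniform <- vapply(all_nodes, function(nd) {
    vals <- trait[tree$tip.label[tips_of(nd)]]
    vals <- vals[!is.na(vals)]
    length(vals) > 0 && all(vals == value)
  }, logical(1))
  parent_of <- function(nd) {
    p <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(p)) p else NA_integer_
  }
  keep <- vapply(all_nodes, function(nd) {
    if (!uniform[nd]) return(FALSE)
    p <- parent_of(nd)
    is.na(p) || !uniform[p]
  }, logical(1))
  lapply(all_nodes[keep], function(nd) sort(tree$tip.label[tips_of(nd)]))
}

# random trait assignment over a random tree, for oracle comparisons
random_annotated_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  n <- sample(c(10, 11, 12, NA), n_tips, replace = TRUE,
              prob = c(0.35, 0.35, 0.2, 0.1))
  list(tree = tree, n = stats::setNames(n, tree$tip.label))
}
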