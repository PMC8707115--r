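test_that("time-tree validation enforces branch lengths, labels, ultrametricity", {
  tree <- attina_timetree()
  expect_s3_class(tree, "phylo")
  expect_equal(length(tree$tip.label), 51L)
  expect_equal(max(ape::node.depth.edgelength(tree)), 55)

  bad <- tree
  bad$tip.label[2] <- bad$tip.label[1]
  expect_error(validate_timetree(bad), "duplicate tip labels")

  notum <- ape::rtree(10)  # random non-ultrametric branch lengths
  expect_error(validate_timetree(notum), "ultrametric")

  nolen <- ape::read.tree(text = "((a,b),c);")
  expect_error(validate_timetree(nolen), "branch lengths")
})

test_that("traits attach to tips by normalised name with a full match report", {
  tree <- attina_timetree()
  rec <- attina_records()
  at <- attach_traits(tree, make_trait_table(rec))
  expect_length(at$report$unmatched_tips, 0)
  expect_equal(sum(!is.na(at$n)), 51L)
  # records absent from the tree are reported, not dropped silently
  expect_true("Apterostigma sp." %in% at$report$unused_traits)
  # reconciliation prefers the newly reported count
  expect_equal(unname(at$n["Cyphomyrmex_transversus"]), 21)
  expect_equal(unname(at$n["Myrmicocrypta_sp."]), 14)
  # first non-missing genome size survives reconciliation
  expect_equal(unname(at$gs["Atta_sexdens"]), 0.33)

  disjoint <- data.frame(taxon = c("Nosuchia primus", "Nosuchia secundus"),
                         n = c(10, 11))
  expect_error(attach_traits(tree, disjoint), "no trait-table taxon matches")
})

test_that("genus fallback fills unmatched tips only when requested", {
  tree <- ape::read.tree(text = "(Atta_fakespecies:5,Atta_sexdens:5);")
  traits <- data.frame(taxon = c("Atta sexdens", "Atta laevigata"),
                       n = c(11, 11), gs_pg = c(0.33, 0.33))
  strict <- attach_traits(tree, traits)
  expect_true(is.na(strict$n["Atta_fakespecies"]))
  loose <- attach_traits(tree, traits, genus_fallback = TRUE)
  expect_equal(unname(loose$n["Atta_fakespecies"]), 11)
  expect_equal(loose$report$genus_fallback, "Atta_fakespecies")
})

test_that("uniform-number clades on the packaged tree match the stasis pattern", {
  at <- attach_traits(attina_timetree(), make_trait_table(attina_records()))
  cl11 <- fixed_number_clades(at, 11)
  expect_gte(nrow(cl11), 2L)
  tipsets <- cl11$tips
  atta_tips <- grep("^Atta_", at$tree$tip.label, value = TRUE)
  amoi_tips <- grep("^Amoimyrmex_", at$tree$tip.label, value = TRUE)
  expect_true(any(vapply(tipsets, function(ts) setequal(ts, atta_tips),
                         logical(1))))
  expect_true(any(vapply(tipsets, function(ts) setequal(ts, amoi_tips),
                         logical(1))))
  # mutually non-nested
  for (i in seq_along(tipsets)) {
    for (j in seq_along(tipsets)) {
      if (i != j) expect_length(intersect(tipsets[[i]], tipsets[[j]]), 0)
    }
  }
  # clades sorted by crown age descending
  expect_true(all(diff(cl11$crown_age) <= 0))
})

test_that("maximal uniform clades equal a brute-force enumeration", {
  for (seed in 1:100) {
    ra <- random_annotated_tree(sample(20:25, 1), seed = seed)
    if (all(is.na(ra$n))) next
    at <- attach_traits(ra$tree,
                        data.frame(taxon = names(ra$n), n = unname(ra$n)))
    for (v in unique(ra$n[!is.na(ra$n)])) {
      got <- vapply(fixed_number_clades(at, v)$tips,
                    function(ts) paste(sort(ts), collapse = "|"), character(1))
      want <- vapply(brute_force_clades(ra$tree, ra$n, v),
                     paste, character(1), collapse = "|")
      expect_identical(sort(got), sort(want))
    }
  }
})

test_that("stasis summaries partition trait tips and report modal numbers", {
  at <- attach_traits(attina_timetree(), make_trait_table(attina_records()))
  ss <- stasis_summary(at)
  # every trait-bearing tip with value n sits in exactly one clade of n's report
  for (k in seq_len(nrow(ss$by_number))) {
    v <- ss$by_number$n[k]
    tips_v <- names(at$n)[!is.na(at$n) & at$n == v]
    listed <- unlist(ss$clades[[as.character(v)]]$tips)
    member <- listed[listed %in% tips_v]
    expect_setequal(member, tips_v)
    expect_equal(anyDuplicated(member), 0L)
  }
  # the 10-12 band recurs in several independent clades
  low_band <- ss$by_number$independent_clade_count[ss$by_number$n %in% c(10, 11)]
  expect_gte(sum(low_band), 4L)
  expect_equal(ss$modal_n, 19)  # 16 uniform Acromyrmex tips dominate tip counts
})

test_that("crown and stem ages are consistent on ultrametric trees", {
  at <- attach_traits(attina_timetree(), make_trait_table(attina_records()))
  ss <- stasis_summary(at)
  for (cl in ss$clades) {
    expect_true(all(cl$crown_age >= 0))
    ok <- !is.na(cl$stem_age)
    expect_true(all(cl$crown_age[ok] <= cl$stem_age[ok]))
    # crown age equals the maximum tip-to-ancestor path length
    ages <- node_ages(at$tree)
    depth <- ape::node.depth.edgelength(at$tree)
    for (i in seq_len(nrow(cl))) {
      nd <- cl$node[i]
      tips <- match(cl$tips[[i]], at$tree$tip.label)
      expect_equal(cl$crown_age[i], max(depth[tips]) - depth[nd],
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate trees give the degenerate clade answers", {
  # star tree, all tips sharing n: a single clade at the root
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  at <- attach_traits(star, data.frame(taxon = letters[1:4], n = rep(9, 4)))
  cl <- fixed_number_clades(at, 9)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$tips[[1]], c("a", "b", "c", "d"))
  # all-distinct numbers: one single-tip clade per number
  at2 <- attach_traits(star, data.frame(taxon = letters[1:4], n = 1:4))
  ss <- stasis_summary(at2)
  expect_true(all(ss$by_number$independent_clade_count == 1L))
  expect_true(all(vapply(ss$clades, function(cl) all(cl$n_tips == 1L),
                         logical(1))))
})

test_that("zero-rate chromosome evolution leaves one root-value clade", {
  tree <- attina_timetree()
  sim <- simulate_chromosome_evolution(
    tree, evol_model(fission_rate = 0, fusion_rate = 0), root_n = 11,
    seed = 4)
  at <- attach_traits(tree, data.frame(taxon = names(sim$tip_n),
                                       n = unname(sim$tip_n)))
  cl <- fixed_number_clades(at, 11)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_tips[1], length(tree$tip.label))
})

test_that("genome-size departures flag multiplicative outliers with context", {
  at <- attach_traits(attina_timetree(), make_trait_table(attina_records()))
  dep <- gs_departures_on_tree(at)
  expect_true("Apterostigma_madidiense" %in% dep$tip)
  expect_equal(dep$direction[dep$tip == "Apterostigma_madidiense"], "high")
  expect_true(all(diff(dep$gs_pg) <= 0))

  # all tips exactly at the centre: nothing flagged
  flat <- attach_traits(at$tree, data.frame(
    taxon = at$tree$tip.label, n = 10,
    gs_pg = 0.38))
  expect_equal(nrow(gs_departures_on_tree(flat)), 0L)
  # factor 1: every tip off-centre flagged
  all_dep <- gs_departures_on_tree(at, factor = 1)
  expect_equal(nrow(all_dep), sum(!is.na(at$gs) & at$gs != 0.38))
})

test_that("annotated Newick export carries trait comments", {
  tree <- ape::read.tree(text = "(Atta_sexdens:5,Atta_laevigata:5);")
  at <- attach_traits(tree, data.frame(taxon = c("Atta sexdens"),
                                       n = 11, gs_pg = 0.33))
  path <- tempfile(fileext = ".nwk")
  on.exit(unlink(path))
  nwk <- write_annotated_newick(at, path)
  expect_match(nwk, "Atta_sexdens\\[&n=11,gs=0.33\\]:")
  expect_identical(readLines(path), nwk)
})
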