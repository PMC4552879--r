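# Maximum-parsimony sample trees on binary mutation matrices.

make_matrix <- function(calls, n_extra_syn = 0L) {
  # cohort table whose calls are exactly `calls` (generous counts)
  all_keys <- sort(unique(unlist(calls)))
  n <- length(all_keys)
  obs <- list(nrm = ob("normal", rep(100L, n), rep(0L, n)))
  for (sid in names(calls)) {
    altv <- ifelse(all_keys %in% calls[[sid]], 40L, 0L)
    obs[[sid]] <- ob(if (sid == "pls") "plasma" else "tumor",
                     rep(100L, n), altv)
  }
  tab <- make_table(obs)
  tab$variants$gene <- all_keys
  key_map <- setNames(variant_keys(tab), all_keys)
  list(table = tab,
       calls = lapply(calls, function(k) unname(key_map[k])),
       key_map = key_map)
}

test_that("mutation matrix has the normal as all-absent outgroup", {
  fx <- make_matrix(list(primary = c("m1", "m2"), met = c("m2", "m3")))
  mm <- build_mutation_matrix(fx$calls, fx$table)
  expect_equal(mm$samples[1], "nrm")
  expect_equal(unname(rowSums(mm$mat)["nrm"]), 0)
  expect_equal(ncol(mm$mat), 3L)
  pats <- apply(mm$mat[c("primary", "met"), ], 2L, paste, collapse = "")
  expect_setequal(unname(pats), c("10", "11", "01"))

  # nonsynonymous filter drops characters
  fx$table$variants$nonsynonymous[1] <- FALSE
  mm2 <- build_mutation_matrix(fx$calls, fx$table, nonsynonymous_only = TRUE)
  expect_equal(ncol(mm2$mat), 2L)
  fx$table$variants$nonsynonymous[] <- FALSE
  expect_error(
    build_mutation_matrix(fx$calls, fx$table, nonsynonymous_only = TRUE),
    "no characters")
})

test_that("Fitch counts match brute-force enumeration on random matrices", {
  set.seed(42)
  for (rep in 1:50) {
    n_tip <- sample(4:6, 1)
    K <- sample(5:25, 1)
    tip_states <- matrix(rbinom(n_tip * K, 1L, 0.5), nrow = n_tip)
    tip_states[1L, ] <- 0L                       # normal outgroup
    topos <- cfexome:::.all_topologies(n_tip)
    e <- topos[[sample(length(topos), 1)]]
    got <- sum(cfexome:::.fitch_pass(e, n_tip, tip_states)$counts)
    want <- brute_force_length(e, n_tip, tip_states)
    expect_equal(got, want)
  }
  # singleton and constant characters
  e <- cfexome:::.all_topologies(4L)[[1L]]
  single <- matrix(c(0L, 1L, 0L, 0L), ncol = 1L)
  expect_equal(sum(cfexome:::.fitch_pass(e, 4L, single)$counts), 1L)
  constant <- matrix(0L, nrow = 4L, ncol = 1L)
  expect_equal(sum(cfexome:::.fitch_pass(e, 4L, constant)$counts), 0L)
})

test_that("Fitch length agrees with phangorn on random instances", {
  skip_if_not_installed(c("phangorn"))
  skip_if_not_installed(c("ape"))
  set.seed(7)
  for (rep in 1:10) {
    n_tip <- sample(4:6, 1)
    K <- 15L
    labels <- c("normal", paste0("s", seq_len(n_tip - 1L)))
    mat <- matrix(rbinom(n_tip * K, 1L, 0.5), nrow = n_tip,
                  dimnames = list(labels, paste0("c", 1:K)))
    mat[1L, ] <- 0L
    tree <- ape::rtree(n_tip, tip.label = sample(labels))
    dat <- phangorn::phyDat(mat, type = "USER", levels = c(0L, 1L))
    want <- phangorn::parsimony(tree, dat)
    mm <- structure(list(samples = labels, mat = mat,
                         nonsynonymous_only = FALSE),
                    class = "mutation_matrix")
    expect_equal(fitch_length(mm, tree), as.integer(want))
  }
})

test_that("best_tree recovers homoplasy-free structure with correct lengths", {
  # trunk 30 shared by all, primary-private 10, met-private 8, plasma = met
  chars <- c(paste0("t", 1:30), paste0("p", 1:10), paste0("m", 1:8))
  fx <- make_matrix(list(
    primary = c(paste0("t", 1:30), paste0("p", 1:10)),
    met = c(paste0("t", 1:30), paste0("m", 1:8)),
    pls = c(paste0("t", 1:30), paste0("m", 1:8))))
  mm <- build_mutation_matrix(fx$calls, fx$table)
  tr <- best_tree(mm)
  expect_equal(tr$total_length, 48L)
  expect_equal(sort(tr$branch_lengths$length), sort(c(0L, 30L, 10L, 8L, 0L)))
  # met and plasma are sisters with zero-length pendant edges
  expect_match(tr$newick, "\\(met:0,pls:0\\)")
  # trunk mutations sit on the edge from the normal side
  expect_equal(tr$branch_lengths$length[
    tr$branch_lengths$parent_label == "nrm"], 30L)

  # identical call sets give a zero-length branch pair
  fx2 <- make_matrix(list(primary = c("a", "b"), met = c("a", "c"),
                          pls = c("a", "c")))
  mm2 <- build_mutation_matrix(fx2$calls, fx2$table)
  tr2 <- best_tree(mm2)
  met_pls <- tr2$branch_lengths$length[
    tr2$branch_lengths$child_label %in% c("met", "pls")]
  expect_equal(met_pls, c(0L, 0L))

  # all-constant characters across non-normal samples
  fx3 <- make_matrix(list(primary = "a", met = "a", pls = "a"))
  mm3 <- build_mutation_matrix(fx3$calls, fx3$table)
  expect_equal(best_tree(mm3)$total_length, 1L)   # one gain on the trunk

  expect_error(best_tree(structure(list(
    samples = paste0("s", 1:9),
    mat = matrix(0L, 9, 1, dimnames = list(paste0("s", 1:9), "c")),
    nonsynonymous_only = FALSE), class = "mutation_matrix")),
    "at most 8")
})

test_that("newick output is canonical, integer-lengthed and parseable", {
  skip_if_not_installed("ape")
  fx <- make_matrix(list(primary = c("a", "b", "c"), met = c("a", "d")))
  mm <- build_mutation_matrix(fx$calls, fx$table)
  tr <- best_tree(mm)
  expect_match(to_newick(tr), "^\\(nrm:0,")
  expect_false(grepl("[.]", to_newick(tr)))   # integer branch lengths
  phy <- ape::read.tree(text = to_newick(tr))
  expect_setequal(phy$tip.label, c("nrm", "primary", "met"))
  expect_equal(sum(phy$edge.length), tr$total_length)

  # invariant under permutation of the input sample order
  mm_perm <- build_mutation_matrix(rev(fx$calls), fx$table)
  expect_equal(to_newick(best_tree(mm_perm)), to_newick(tr))

  # round trip: lengths recoverable via fitch on the same matrix
  expect_equal(fitch_length(mm, tr), tr$total_length)
})
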