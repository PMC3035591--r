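test_that("split counting excludes missing labels and keeps sums consistent", {
  lab <- c(A = "class1", B = "class1", C = "class2", D = "class2")
  rec <- split_counts(list(c("A", "B"), c("C", "D")), lab)
  expect_equal(rec$N, 4)
  expect_equal(unname(rec$n), c(2, 2))
  expect_equal(unname(rec$m), c(2, 2))
  expect_equal(unname(rec$M), rbind(c(2L, 0L), c(0L, 2L)))

  lab2 <- c(A = "class1", B = NA, C = "class2", D = "class2")
  rec2 <- split_counts(list(c("A", "B"), c("C", "D")), lab2)
  expect_equal(rec2$N, 3)
  expect_equal(unname(rec2$n), c(1, 2))
  expect_equal(unname(rec2$m), c(1, 2))

  lab3 <- c(A = NA, B = NA, C = NA, D = NA)
  rec3 <- split_counts(list(c("A", "B"), c("C", "D")), lab3)
  expect_equal(rec3$N, 0)
  expect_equal(rec3$score, 0)
})

test_that("split probabilities match the exhaustive assignment oracle", {
  # N=2 perfect singleton split: 2 equally likely assignments
  rec <- list(N = 2, n = c(1, 1), m = c(1, 1), M = rbind(c(1, 0), c(0, 1)))
  expect_equal(split_probability(rec), 0.5)
  expect_equal(split_probability(rec),
               enum_split_probability(c(1L, 2L), rec$m, rec$M))

  # N=4 perfect split: 1 of choose(4,2)=6 subset choices
  rec4 <- list(N = 4, n = c(2, 2), m = c(2, 2), M = rbind(c(2, 0), c(0, 2)))
  expect_equal(split_probability(rec4), 1 / 6)
  expect_equal(split_probability(rec4),
               enum_split_probability(c(1L, 1L, 2L, 2L), rec4$m, rec4$M))

  # single class: only one possible table
  rec1 <- list(N = 4, n = 4, m = c(2, 2), M = rbind(2, 2))
  expect_equal(split_probability(rec1), 1)

  # random small configurations against the oracle, incl. 3-way splits
  set.seed(51)
  for (i in 1:12) {
    N <- sample(3:7, 1); kappa <- sample(2:3, 1); l <- sample(2:3, 1)
    pool <- sample(seq_len(kappa), N, replace = TRUE)
    cuts <- sort(sample(0:N, l - 1, replace = TRUE))
    m <- diff(c(0, cuts, N))
    idx <- split(seq_len(N), factor(rep(seq_len(l), m), levels = seq_len(l)))
    M <- t(vapply(seq_len(l), function(j)
      tabulate(pool[idx[[j]]], nbins = kappa), integer(kappa)))
    rec <- list(N = N, n = tabulate(pool, nbins = kappa), m = m, M = M)
    expect_equal(split_probability(rec),
                 enum_split_probability(pool, m, M), tolerance = 1e-12)
  }
})

test_that("inconsistent count tables are rejected", {
  expect_error(splitting_score(list(N = 4, n = c(2, 2), m = c(2, 2),
                                    M = rbind(c(2, 1), c(0, 2)))),
               "inconsistent")
})

test_that("splitting scores are minus-log probabilities and grow with cluster size", {
  rec <- list(N = 2, n = c(1, 1), m = c(1, 1), M = rbind(c(1, 0), c(0, 1)))
  expect_equal(splitting_score(rec), log(2), tolerance = 1e-9)
  # perfect two-class splits: ln 6 < ln 20 < ln 70 as N = 4, 6, 8
  perfect <- function(N) {
    h <- N / 2
    splitting_score(list(N = N, n = c(h, h), m = c(h, h),
                         M = rbind(c(h, 0), c(0, h))))
  }
  expect_equal(perfect(4), log(6), tolerance = 1e-9)
  expect_equal(perfect(6), log(20), tolerance = 1e-9)
  expect_equal(perfect(8), log(70), tolerance = 1e-9)
  expect_true(perfect(4) < perfect(6) && perfect(6) < perfect(8))
  # probability-1 split scores zero
  expect_equal(splitting_score(list(N = 3, n = 3, m = c(1, 2), M = rbind(1, 2))), 0)
})

test_that("log-gamma arithmetic survives clusters with thousands of members", {
  N <- 4000; h <- N / 2
  s <- splitting_score(list(N = N, n = c(h, h), m = c(h, h),
                            M = rbind(c(h, 0), c(0, h))))
  expect_true(is.finite(s))
  # Stirling cross-check: ln C(4000, 2000) via lchoose
  expect_equal(s, lchoose(N, h), tolerance = 1e-9)
})

test_that("the Tree Index matches hand evaluation and degenerate conventions", {
  expect_equal(tree_index(quartet_tree(), quartet_labels())$ti,
               log(6) * sqrt(2) / 3, tolerance = 1e-12)
  # all labels one class: all scores zero
  one <- c(A = "x", B = "x", C = "x", D = "x")
  expect_equal(tree_index(quartet_tree(), one)$ti, 0)
  # single split: standard deviation of one value
  pair <- read_tree("(A,B);")
  expect_equal(tree_index(pair, c(A = "1", B = "2"))$ti, 0)
  expect_error(tree_index(read_tree("A;"), c(A = "1")), "2 leaves")
  expect_error(tree_index(quartet_tree(), c(A = "1", B = "2")), "length|missing")
})

test_that("TI is invariant to class names, child order and split order", {
  set.seed(61)
  for (i in 1:10) {
    rl <- random_labeled_tree(sample(6:12, 1), sample(2:4, 1), missing_frac = 0.2)
    ti1 <- tree_index(rl$tree, rl$labels)$ti
    # permute class identities
    relabeled <- rl$labels
    cls <- unique(stats::na.omit(rl$labels))
    map <- stats::setNames(sample(paste0("z", seq_along(cls))), cls)
    relabeled[!is.na(relabeled)] <- map[relabeled[!is.na(relabeled)]]
    expect_equal(tree_index(rl$tree, relabeled)$ti, ti1, tolerance = 1e-12)
    # rotate children (ladderize + rotate root): same TI
    rot <- ape::rotate(rl$tree, node = ape::Ntip(rl$tree) + 1L)
    expect_equal(tree_index(rot, rl$labels)$ti, ti1, tolerance = 1e-12)
    lad <- ape::ladderize(rl$tree)
    expect_equal(tree_index(lad, rl$labels)$ti, ti1, tolerance = 1e-12)
  }
})

test_that("leaf placement of missing-labelled samples never changes the TI", {
  # same induced structure on the labelled leaves {A=1, B=1, C=2}, with the
  # missing-labelled leaf x grafted at three different positions
  lab <- c(A = "1", B = "1", C = "2", x = NA)
  placements <- c("(((A,x),B),C);", "(((A,B),x),C);", "((A,B),(x,C));")
  tis <- vapply(placements, function(nwk) tree_index(read_tree(nwk), lab)$ti,
                numeric(1))
  expect_equal(tis[[1]], log(3) * sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(unname(tis), rep(tis[[1]], 3), tolerance = 1e-12)

  # larger case: two missing leaves moved between the two sides of the root
  la <- c(A = "1", B = "1", C = "2", D = "2", E = NA, F = NA)
  t_ef_right <- read_tree("(((A,B),(C,D)),(E,F));")
  t_ef_split <- read_tree("((((A,E),B),(C,D)),F);")
  expect_equal(tree_index(t_ef_right, la)$ti, tree_index(t_ef_split, la)$ti,
               tolerance = 1e-12)
})

test_that("the raw TI inflates with the number of classes on random labels", {
  set.seed(81)
  tr <- ape::rtree(30)
  mean_ti <- vapply(c(2, 5), function(kappa) {
    mean(vapply(1:200, function(i) {
      lab <- sample(paste0("c", seq_len(kappa)), 30, replace = TRUE)
      names(lab) <- tr$tip.label
      tree_index(tr, lab)$ti
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_ti[2], mean_ti[1])
})

test_that("degenerate splits can be skipped from R on request", {
  tr <- read_tree("(((A,B),C),(D,E));")
  lab <- c(A = "1", B = "2", C = NA, D = NA, E = NA)
  inc <- tree_index(tr, lab, degenerate = "include")
  skp <- tree_index(tr, lab, degenerate = "skip")
  expect_equal(inc$R, 4)
  expect_lt(skp$R, inc$R)
  expect_false(isTRUE(all.equal(inc$ti, skp$ti)))
})
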