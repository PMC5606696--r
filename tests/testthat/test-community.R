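test_that("pairwise identity counts matches over the global alignment", {
  set.seed(11)
  s100 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  expect_equal(pairwise_identity(s100, s100), 1.0)

  v <- strsplit(s100, "")[[1]]
  v[37] <- setdiff(c("A", "C", "G", "T"), v[37])[1]
  one_off <- paste(v, collapse = "")
  expect_equal(pairwise_identity(s100, one_off), 0.99)

  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity("ACGT", "ACGA"),
               pairwise_identity("ACGA", "ACGT"))
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("greedy OTU clustering groups near-identical clones", {
  lib <- clone_library("five", stats::setNames(
    rep(strrep("ACGT", 30), 5), paste0("c", 1:5)))
  ot <- cluster_otus(lib)
  expect_length(ot$otus, 1)
  expect_length(ot$otus[[1]]$members, 5)

  # two founder groups at ~90% between, 100% within -> two OTUs
  set.seed(12)
  f1 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
              collapse = "")
  v <- strsplit(f1, "")[[1]]
  idx <- sample(100, 10)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  f2 <- paste(v, collapse = "")
  lib2 <- clone_library("two", c(a1 = f1, a2 = f1, b1 = f2, b2 = f2))
  ot2 <- cluster_otus(lib2, threshold = 0.99)
  expect_length(ot2$otus, 2)
  expect_setequal(ot2$otus[[1]]$members, c("a1", "a2"))
  expect_setequal(ot2$otus[[2]]$members, c("b1", "b2"))
})

test_that("clustering matches an independent greedy oracle and partitions", {
  set.seed(13)
  for (rep in 1:5) {
    lib <- random_library(n = 20, len = 120)
    ot <- cluster_otus(lib, threshold = 0.99)
    # partition: every clone exactly once
    members <- unlist(lapply(ot$otus, `[[`, "members"))
    expect_setequal(members, names(lib$sequences))
    expect_equal(length(members), length(unique(members)))
    # same partition as the hamming-identity greedy oracle
    oracle <- oracle_greedy_otus(unname(lib$sequences), 0.99)
    got <- integer(length(lib$sequences))
    for (k in seq_along(ot$otus)) {
      got[match(ot$otus[[k]]$members, names(lib$sequences))] <- k
    }
    expect_equal(got, oracle)
  }
})

test_that("raising the identity threshold never decreases OTU count", {
  set.seed(14)
  for (rep in 1:3) {
    lib <- random_library(n = 15, len = 100, copy_mut = 0.03)
    counts <- vapply(c(0.80, 0.90, 0.95, 0.99),
                     function(th) length(cluster_otus(lib, th)$otus),
                     integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("clade assignment picks the closest reference above the cutoff", {
  panel <- make_clade_panel()
  hit <- assign_clade(panel$sequence[panel$clade == "IIB"], panel)
  expect_identical(hit$clade, "IIB")
  expect_equal(hit$identity, 1.0)
  expect_false(hit$tie)

  set.seed(15)
  rand <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  expect_identical(assign_clade(rand, panel)$clade, "unassigned")

  # a clone 2% mutated away from the IA reference still assigns to IA
  sp <- synth_spec(seed = 3, mutation_rate = 0.02,
                   composition_truth = list("Run A" = c(IA = 1)),
                   clones_per_run = 5L, run_p = 500,
                   plateau_removal = 0, cod_fraction_remaining = 0.02)
  g <- gen_clone_library(sp, 1, panel)
  for (sq in g$library$sequences) {
    expect_identical(assign_clade(sq, panel)$clade, "IA")
  }
})

test_that("composition tables reproduce the printed percentages", {
  run1 <- composition(c(rep("IA", 8), rep("IIA", 3), rep("IIB", 2)), "Run 1")
  expect_equal(run1$percent[["IA"]], 62)  # 8/13 = 61.5% -> 62
  expect_equal(run1$counts[["IA"]], 8L)
  expect_equal(run1$type_percent[["Type I"]], 62)

  run3 <- composition(c(rep("IIB", 20), rep("IIC", 2), rep("IID", 2)),
                      "Run 3")
  expect_equal(run3$percent[["IIB"]], 83)  # 20/24 = 83.3% -> 83
  expect_equal(run3$type_percent[["Type II"]], 100)

  run5 <- composition(rep("IA", 15), "Run 5")
  expect_equal(run5$percent[["IA"]], 100)

  expect_error(composition(character(0)), "no clones")
})

test_that("composition percentages sum to 100 within rounding", {
  set.seed(16)
  clades <- c("IA", "IIA", "IIB")  # study-like three-clade tables
  for (rep in 1:20) {
    n <- sample(13:24, 1)
    assig <- sample(clades, n, replace = TRUE)
    comp <- composition(assig)
    expect_lte(abs(sum(comp$percent) - 100), 1)
    expect_lte(abs(sum(comp$type_percent) - 100), 1)
  }
})

test_that("synthetic libraries are recovered to exact truth counts", {
  panel <- make_clade_panel()
  sp <- synth_spec(seed = 1)
  for (run in seq_along(sp$run_ids)) {
    g <- gen_clone_library(sp, run, panel)
    assignments <- assign_library(g$library, panel)
    # per-clone truth recovery
    expect_identical(assignments, g$truth)
    comp <- composition(assignments, sp$run_ids[run])
    expect_equal(comp$counts[names(g$counts)], g$counts)
    expect_equal(comp$n_clones, sp$clones_per_run[run])
  }
})
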