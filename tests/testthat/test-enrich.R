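test_that("set overlap partitions exactly and reports the shared fraction", {
  a <- paste0("p", 1:79)
  b <- paste0("p", c(1:33, 100:160))   # |B| = 94, |A ∩ B| = 33
  v <- overlap_sets(a, b)
  expect_equal(v$only_a, 46L)
  expect_equal(v$only_b, 61L)
  expect_equal(v$shared, 33L)
  expect_equal(round(100 * v$shared_fraction_a, 1), 41.8)
  # partition conservation
  expect_equal(v$only_a + v$shared, length(unique(a)))
  expect_equal(v$only_b + v$shared, length(unique(b)))

  d <- overlap_sets(c("x", "y"), c("z"))
  expect_equal(d$shared, 0L); expect_equal(d$shared_fraction_a, 0)

  sub <- overlap_sets(c("x", "y"), c("x", "y", "z"))
  expect_equal(sub$shared_fraction_a, 1)

  expect_error(overlap_sets(character(0), "a"), "empty")
})

test_that("GMT files round-trip", {
  sets <- tibble::tibble(
    set_id = c("PW1", "PW2"),
    label = c("glycolysis", "tca cycle"),
    members = list(c("a", "b", "c"), c("b", "d"))
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$set_id, sets$set_id)
  expect_equal(back$label, sets$label)
  expect_equal(back$members, sets$members)
  writeLines("PW3\tno members", path)
  expect_error(read_gmt(path), "without members")
})

test_that("hypergeometric p matches closed-form and boundary cases", {
  uni <- paste0("g", 1:10)
  sets <- tibble::tibble(set_id = c("S", "ALL"), label = c("s", "all"),
                         members = list(paste0("g", 1:5), uni))
  hits <- paste0("g", 1:3)          # all 3 hits inside the 5-member set
  res <- hypergeometric_enrichment(hits, sets, uni)
  expect_equal(res$p_value[res$set_id == "S"], 10 / 120, tolerance = 1e-12)
  expect_equal(res$p_value[res$set_id == "ALL"], 1)   # set = universe
  # zero overlap has upper-tail p = 1
  res0 <- hypergeometric_enrichment("g9", sets[1, ], uni)
  expect_equal(res0$p_value, 1)
  expect_error(hypergeometric_enrichment("nope", sets, uni), "outside")
})

test_that("enrichment p equals exhaustive subset enumeration for small universes", {
  set.seed(21)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    uni <- paste0("g", 1:N)
    sets <- tibble::tibble(set_id = "S", label = "s",
                           members = list(paste0("g", 1:K)))
    hits <- paste0("g", sample(N, n))
    res <- hypergeometric_enrichment(hits, sets, uni)
    k <- length(intersect(hits, sets$members[[1]]))
    expect_equal(res$p_value, enum_hyper_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("BH q-values are monotone in ranked p and never below p", {
  set.seed(22)
  uni <- paste0("g", 1:60)
  sets <- tibble::tibble(
    set_id = paste0("S", 1:12), label = paste0("s", 1:12),
    members = lapply(1:12, function(i) sample(uni, sample(5:20, 1)))
  )
  res <- hypergeometric_enrichment(sample(uni, 15), sets, uni)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
})

test_that("random hit sets are not systematically enriched", {
  set.seed(23)
  uni <- paste0("g", 1:200)
  sets <- tibble::tibble(
    set_id = paste0("S", 1:40), label = paste0("s", 1:40),
    members = lapply(1:40, function(i) sample(uni, 25))
  )
  rates <- replicate(25, {
    res <- hypergeometric_enrichment(sample(uni, 30), sets, uni)
    mean(res$p_value < 0.05)
  })
  n_tests <- 25 * 40
  expect_lte(mean(rates), 0.05 + 3 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("joint pathway testing pools universes and reduces cleanly", {
  prot_u <- paste0("p", 1:8)
  met_u <- paste0("m", 1:2)
  sets <- tibble::tibble(set_id = "J", label = "joint",
                         members = list(c("p1", "p2", "p3", "m1", "m2")))
  # 3 pooled hits, all inside the 5-member pathway, universe 10
  res <- joint_pathway_enrichment(c("p1", "p2"), "m1", sets, prot_u, met_u)
  expect_equal(res$p_value, 10 / 120, tolerance = 1e-12)
  expect_equal(res$k_protein, 2L)
  expect_equal(res$k_metabolite, 1L)

  # protein-only pathway behaves exactly like the plain test
  psets <- tibble::tibble(set_id = "P", label = "prot",
                          members = list(c("p1", "p2", "p3")))
  joint <- joint_pathway_enrichment(c("p1", "p2"), character(0), psets,
                                    prot_u, met_u)
  plain <- hypergeometric_enrichment(c("p1", "p2"), psets, c(prot_u, met_u))
  expect_equal(joint$p_value, plain$p_value)
  expect_equal(joint$k_metabolite, 0L)

  expect_error(
    joint_pathway_enrichment("p1", character(0), sets, prot_u, c("p1", "m1")),
    "both universes"
  )
})
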