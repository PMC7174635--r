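# Enrichment scoring, the synonymous-control null, hit calls, pleiotropy.

test_that("log2 enrichment matches direct arithmetic", {
  expect_equal(log2Enrichment(50, 1000, 200, 1000, pseudocount = 0), 2)
  expect_equal(log2Enrichment(30, 300, 100, 1000, pseudocount = 0), 0)
  # zero post count with the default pseudocount
  expect_equal(log2Enrichment(50, 1000, 0, 1000),
               log2(0.5 / 50.5), tolerance = 1e-12)
  expect_equal(log2(0.5 / 50.5), -6.658211, tolerance = 1e-6)
  # alpha = 0 with a zero count -> NA with warning
  expect_warning(f <- log2Enrichment(0, 100, 5, 100, pseudocount = 0),
                 "undefined")
  expect_true(is.na(f))
})

test_that("enrichment is antisymmetric and depth-invariant at alpha = 0", {
  set.seed(601)
  for (i in 1:50) {
    a <- sample(1:500, 1); b <- sample(1:500, 1)
    ta <- sample(1000:5000, 1); tb <- sample(1000:5000, 1)
    f <- log2Enrichment(a, ta, b, tb, pseudocount = 0)
    expect_equal(log2Enrichment(b, tb, a, ta, pseudocount = 0), -f)
    k <- sample(2:10, 1)
    expect_equal(log2Enrichment(a, ta * k, b, tb * k, pseudocount = 0), f)
  }
})

test_that("the control null gives mean + k*SD with sample SD", {
  ft <- data.frame(cassette_id = paste0("c", 1:4),
                   is_control = c(TRUE, TRUE, TRUE, FALSE),
                   condition = "drug",
                   fitness = c(-1, 0, 1, 5))
  nm <- synonymousNull(ft, k = 2)
  expect_equal(nm@mean, 0)
  expect_equal(nm@sd, 1)  # sample SD of {-1, 0, 1}
  expect_equal(nullCutoff(nm), 2)
  # constant controls: cutoff = the constant
  ftc <- ft; ftc$fitness <- c(0.3, 0.3, 0.3, 5)
  expect_equal(nullCutoff(synonymousNull(ftc, k = 2)), 0.3)
  # < 2 controls -> error
  expect_error(synonymousNull(ft[3:4, ], k = 2), "fewer than 2")
})

test_that("large control sets recover the generating null", {
  set.seed(602)
  n <- 1000
  ft <- data.frame(cassette_id = paste0("c", 1:n), is_control = TRUE,
                   condition = "drug", fitness = rnorm(n))
  nm <- synonymousNull(ft, k = 2)
  expect_lt(abs(nm@mean - 0), 3 / sqrt(n))            # SE of the mean
  expect_lt(abs(nm@sd - 1), 3 / sqrt(2 * (n - 1)))    # SE of the SD
})

test_that("hits require fitness strictly above the cutoff", {
  ft <- data.frame(
    cassette_id = paste0("c", 1:6),
    is_control = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    condition = "drug",
    fitness = c(-1, 1, 2.1, 1.9, 2.0, 10))
  # controls {-1, 1}: mean 0, sd sqrt(2); use an explicit k for cutoff 2
  nm <- synonymousNull(ft, k = sqrt(2))
  expect_equal(nullCutoff(nm), 2)
  hits <- callHits(ft, nm)
  hit <- stats::setNames(hits$hit, hits$cassette_id)
  expect_true(hit[["c3"]])        # 2.1 > 2
  expect_false(hit[["c4"]])       # 1.9
  expect_false(hit[["c5"]])       # exactly at the cutoff: no hit
  # sorted by descending fitness
  expect_equal(hits$cassette_id[1], "c6")
  # a control above the cutoff is still not a hit
  ft2 <- rbind(ft, data.frame(cassette_id = "ctrlHigh", is_control = TRUE,
                              condition = "drug", fitness = 99))
  expect_false(any(callHits(ft2, nm)$hit & callHits(ft2, nm)$is_control))
})

test_that("conditions without a null are reported not-assayed", {
  ft <- data.frame(cassette_id = c("a", "b"), is_control = FALSE,
                   condition = c("drug1", "drug2"), fitness = c(3, 4))
  nm <- new("ScreenNull", condition = "drug1", mean = 0, sd = 1, k = 2,
            cutoff = 2, nControls = 10L)
  expect_warning(hits <- callHits(ft, nm), "drug2")
  expect_true(hits$hit[hits$condition == "drug1"])
  expect_true(is.na(hits$hit[hits$condition == "drug2"]))
})

test_that("under a pure null few controls exceed mean + 2 SD", {
  set.seed(603)
  fracs <- vapply(1:20, function(i) {
    sc <- rnorm(200)
    ft <- data.frame(cassette_id = seq_along(sc), is_control = TRUE,
                     condition = "null", fitness = sc)
    controlExceedance(ft, synonymousNull(ft, k = 2))
  }, numeric(1))
  expect_true(all(fracs < 0.10))
  expect_gt(mean(fracs), 0)  # upper tail is small but not empty
})

test_that("pleiotropy matrix summarizes hits across conditions", {
  hits <- data.frame(
    gene = "g", variant = c("g A1V", "g A1V", "g A1V", "g K2E"),
    condition = c("d1", "d2", "d3", "d1"),
    hit = c(TRUE, TRUE, FALSE, TRUE),
    fitness = c(3, 2.5, 0.4, 4))
  pm <- pleiotropyMatrix(hits)
  row <- pm$matrix[pm$matrix$variant == "g A1V", ]
  expect_equal(unlist(row[c("d1", "d2", "d3")], use.names = FALSE),
               c("hit", "hit", "no-hit"))
  # variant assayed in one condition only
  row2 <- pm$matrix[pm$matrix$variant == "g K2E", ]
  expect_equal(unlist(row2[c("d2", "d3")], use.names = FALSE),
               rep("not-assayed", 2))
  expect_equal(pm$shared$variant, "g A1V")
  expect_equal(pm$shared$conditions, "d1,d2")
})

test_that("the packaged hit fixture shows soxR I120E shared across drugs", {
  fx <- utils::read.delim(system.file("extdata", "table2_hits.tsv",
                                      package = "cassetteScreen"))
  hits <- data.frame(gene = fx$gene,
                     variant = paste(fx$gene, fx$mutation),
                     condition = fx$antibiotic,
                     hit = TRUE, fitness = fx$fitness_score)
  pm <- pleiotropyMatrix(hits)
  expect_true("soxR I120E" %in% pm$shared$variant)
  expect_equal(
    pm$shared$conditions[pm$shared$variant == "soxR I120E"],
    "Doxycycline,Thiamphenicol")
  # 7 distinct variants over 3 conditions in the fixture
  expect_equal(nrow(pm$matrix), 7)
  expect_equal(sort(unique(hits$condition)),
               c("Doxycycline", "Gentamicin", "Thiamphenicol"))
})

test_that("fitness tables join counts with the design and score them", {
  counts <- matrix(c(100L, 50L, 50L, 400L, 50L, 50L), nrow = 3,
                   dimnames = list(c("m1", "s1", "s2"), c("pre", "post")))
  ct <- new("CassetteCounts", counts = counts,
            unmapped = c(pre = 0, post = 0), ambiguous = c(pre = 0, post = 0),
            total = c(pre = 200, post = 500))
  design <- data.frame(cassette_id = c("m1", "s1", "s2"), gene = "g",
                       position = 1L, wt_aa = "A",
                       mut_aa = c("V", "A", "A"),
                       is_control = c(FALSE, TRUE, TRUE))
  ft <- fitnessTable(ct, design, condition = "drug", pseudocount = 0)
  # m1: (400/500) / (100/200) = 1.6 -> log2 = 0.678; controls: 0.1/0.25
  expect_equal(ft$fitness[1], log2(0.8 / 0.5))
  expect_equal(ft$fitness[2], log2(0.1 / 0.25))
  expect_equal(ft$condition, rep("drug", 3))
})
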