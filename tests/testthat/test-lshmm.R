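test_that("posterior is symmetric for identical panel haplotypes", {
  al <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0))
  post <- forwardBackward(c(1, 1, 0, 0), al, c(1e5, 2e5, 3e5, 4e5), HmmParams())
  expect_equal(unname(post), matrix(0.5, 4, 2))
})

test_that("posterior locks onto an exact template", {
  # every other haplotype differs from haplotype 1 at all three sites
  al <- rbind(c(1, 0, 1), c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  post <- forwardBackward(al[1, ], al, c(1e5, 5e5, 9e5),
                          HmmParams(recombScale = 0.1, copyError = 1e-6))
  expect_true(all(post[, 1] > 0.99))
  oracle <- bruteForcePosterior(al[1, ], al, c(1e5, 5e5, 9e5),
                                HmmParams(recombScale = 0.1, copyError = 1e-6))
  expect_equal(post, oracle, tolerance = 1e-10)
})

test_that("forward-backward equals exhaustive path enumeration on random instances", {
  set.seed(42)
  for (i in 1:25) {
    H <- sample(2:6, 1)
    M <- sample(1:6, 1)
    al <- matrix(rbinom(H * M, 1, runif(1, 0.2, 0.8)), H, M)
    tg <- rbinom(M, 1, 0.5)
    pos <- sort(sample.int(2e6, M))
    pr <- HmmParams(recombScale = runif(1, 0.1, 20),
                    copyError = runif(1, 1e-4, 0.3),
                    minSwitch = sample(c(0, 1e-5, 0.01), 1))
    post <- forwardBackward(tg, al, pos, pr)
    expect_equal(rowSums(post), rep(1, M), tolerance = 1e-9)
    expect_equal(post, bruteForcePosterior(tg, al, pos, pr), tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(forwardBackward(integer(0), matrix(0, 2, 0), integer(0), HmmParams()),
               "at least one typed site")
  expect_error(forwardBackward(1L, matrix(1, 1, 1), 1L, HmmParams()),
               "two reference haplotypes")
})

test_that("interpolation follows the distance-weight rule", {
  post <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  # midway
  mid <- interpolatePosteriors(post, c(100, 300), c(100, 200, 300))
  expect_equal(mid[2, ], c(0.5, 0.5))
  # dL = 1, dR = 3 -> weights 0.75/0.25
  un <- interpolatePosteriors(post, c(100, 104), c(100, 101, 104))
  expect_equal(un[2, ], 0.75 * post[1, ] + 0.25 * post[2, ])
  # outside the typed range: nearest typed posterior
  out <- interpolatePosteriors(post, c(100, 300), c(50, 100, 300, 400))
  expect_equal(out[1, ], post[1, ])
  expect_equal(out[4, ], post[2, ])
  expect_error(interpolatePosteriors(post, c(100, 300), c(200, 300)),
               "subset")
})

test_that("dosages from posteriors follow point-mass and normalization rules", {
  al <- rbind(c(0, 1), c(1, 1))
  post <- rbind(c(1, 0), c(0.25, 0.75))
  d <- dosageFromPosteriors(post, al)
  expect_equal(d[1], 0)      # point mass on haplotype 1, allele 0
  expect_equal(d[2], 1)      # all panel alleles 1
  expect_equal(dosageFromPosteriors(rbind(c(0.25, 0.75)),
                                    cbind(c(0, 1))), 0.75)
})

test_that("estimated R2 matches its defining variance ratio", {
  expect_equal(estimatedR2(rep(0.5, 6)), 0)
  hard <- c(1, 1, 0, 0, 1, 0, 0, 0)
  expect_equal(estimatedR2(hard), 1)
  d <- c(0.9, 0.1, 0.9, 0.1, 1.0, 0.0)
  p <- mean(d)
  expect_equal(estimatedR2(d), mean((d - p)^2) / (p * (1 - p)))
  expect_equal(estimatedR2(d), 0.76)
  # diploid variant: denominator 2p(1-p) on genotype dosages
  g <- c(1.8, 0.2, 1.8, 0.2, 2, 0)
  pg <- mean(g) / 2
  expect_equal(estimatedR2(g, diploid = TRUE), mean((g - mean(g))^2) / (2 * pg * (1 - pg)))
  expect_equal(estimatedR2(c(0, 0, 0)), 0)
})

test_that("imputeCohort matches the brute-force posterior pipeline on a small instance", {
  set.seed(9)
  al <- matrix(rbinom(4 * 5, 1, 0.5), 4, 5)
  pos <- c(10e3, 200e3, 430e3, 700e3, 950e3)
  panel <- HaplotypePanel(al, pos, sampleIds = rep(c("P1", "P2"), each = 2))
  tgAll <- matrix(rbinom(2 * 5, 1, 0.5), 2, 5)
  typed <- c(2L, 4L)
  tg <- HaplotypePanel(tgAll[, typed, drop = FALSE], pos[typed],
                       sampleIds = rep("T1", 2),
                       haplotypeLabels = c("T1_1", "T1_2"))
  pr <- HmmParams(recombScale = 3, copyError = 0.01)
  dose <- imputeCohort(tg, panel, pr)
  for (h in 1:2) {
    oracle <- bruteForcePosterior(tgAll[h, typed], al[, typed], pos[typed], pr)
    full <- interpolatePosteriors(oracle, pos[typed], pos)
    expect_equal(unname(haplotypeDosage(dose)[h, ]),
                 unname(dosageFromPosteriors(full, al)), tolerance = 1e-10)
  }
  expect_equal(genotypeDosage(dose),
               haplotypeDosage(dose)[1, , drop = FALSE] +
                 haplotypeDosage(dose)[2, , drop = FALSE])
  expect_identical(typedSites(dose), seq_len(5) %in% typed)
})

test_that("allele or site mismatches between target and panel are reconciliation errors", {
  al <- matrix(rbinom(4 * 3, 1, 0.5), 4, 3)
  panel <- HaplotypePanel(al, c(100, 200, 300))
  tgBadSite <- HaplotypePanel(al[1:2, 1:2], c(100, 250))
  expect_error(imputeCohort(tgBadSite, panel), "absent from the panel")
  tgBadAllele <- HaplotypePanel(al[1:2, 1:2], c(100, 200),
                                ref = c("A", "G"), alt = c("C", "T"))
  expect_error(imputeCohort(tgBadAllele, panel), "allele mismatch.*chr1:200")
})

test_that("scaled recursion survives very long marker sets", {
  set.seed(13)
  M <- 1e5
  al <- matrix(rbinom(4 * M, 1, 0.5), 4, M)
  tg <- al[1, ]
  pos <- sort(sample.int(2e8, M))
  post <- forwardBackward(tg, al, pos, HmmParams(copyError = 1e-4))
  expect_false(anyNA(post))
  expect_equal(range(abs(rowSums(post) - 1))[2], 0, tolerance = 1e-9)
})
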