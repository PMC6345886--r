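test_that("the untreated gate encloses at least the target fraction, minimally", {
  gen <- generate_facs_sample(n = 20000, positive_fraction = 0, seed = 101)
  gate <- build_mtkeima_gate(gen$sample, target_fraction = 99.8)
  enclosed <- 100 * mean(in_gate(gate, gen$sample))
  expect_gte(enclosed, 99.8)
  expect_lte(enclosed, 100)
  # minimality: retracting the edge by one event's projection drops below target
  pts <- mitoamp:::.gate_coords(gen$sample)
  s <- drop((pts - rep(gate$centre, each = nrow(pts))) %*% gate$normal)
  k <- ceiling(0.998 * length(s))
  retracted <- gate
  retracted$offset <- sort(s)[k - 1]
  retracted$vertices <- gate$vertices -
    rep((gate$offset - retracted$offset) * gate$normal, each = 3)
  expect_lt(100 * mean(in_gate(retracted, gen$sample)), 99.8)
})

test_that("a 100% target encloses every event", {
  gen <- generate_facs_sample(n = 2000, positive_fraction = 0, seed = 5)
  gate <- build_mtkeima_gate(gen$sample, target_fraction = 100)
  expect_identical(sum(in_gate(gate, gen$sample)), 2000L)
})

test_that("the builder sample itself reads at most the complement fraction", {
  gen <- generate_facs_sample(n = 20000, positive_fraction = 0, seed = 101)
  gate <- build_mtkeima_gate(gen$sample, 99.8)
  expect_lte(percent_positive(gen$sample, gate), 0.2)
})

test_that("a 40% acidified mixture reads 40 +/- 2 percent positive", {
  untr <- generate_facs_sample(n = 20000, positive_fraction = 0, seed = 101)
  gate <- build_mtkeima_gate(untr$sample, 99.8)
  mix <- generate_facs_sample(n = 20000, positive_fraction = 40, seed = 202)
  expect_identical(sum(mix$truth$acidified), 8000L)
  pct <- percent_positive(mix$sample, gate)
  expect_gt(pct, 38)
  expect_lt(pct, 42)
})

test_that("gate construction is deterministic and order-invariant", {
  gen <- generate_facs_sample(n = 5000, positive_fraction = 10, seed = 9)
  untr <- generate_facs_sample(n = 5000, positive_fraction = 0, seed = 10)
  gate1 <- build_mtkeima_gate(untr$sample, 99.8)
  gate2 <- build_mtkeima_gate(untr$sample, 99.8)
  expect_identical(gate1$vertices, gate2$vertices)
  p1 <- percent_positive(gen$sample, gate1)
  set.seed(33)
  perm <- gen$sample[sample.int(nrow(gen$sample)), ]
  expect_equal(percent_positive(facs_sample(perm), gate1), p1)
})

test_that("shifting 561 intensities upward never decreases percent positive", {
  untr <- generate_facs_sample(n = 5000, positive_fraction = 0, seed = 10)
  gate <- build_mtkeima_gate(untr$sample, 99.8)
  smp <- generate_facs_sample(n = 5000, positive_fraction = 20, seed = 11)$sample
  p0 <- percent_positive(smp, gate)
  for (shift in c(50, 500, 5000)) {
    shifted <- smp
    shifted$ex561_em670 <- shifted$ex561_em670 + shift
    expect_gte(percent_positive(facs_sample(shifted), gate), p0)
  }
})

test_that("degenerate clouds and empty samples raise errors", {
  flat <- facs_sample(data.frame(ex488_em695 = rep(100, 200),
                                 ex561_em670 = rep(10, 200)))
  expect_error(build_mtkeima_gate(flat), "degenerate")
  small <- facs_sample(data.frame(ex488_em695 = runif(10, 1, 2),
                                  ex561_em670 = runif(10, 1, 2)))
  expect_error(build_mtkeima_gate(small), ">= 100")
})

test_that("gate JSON round trip preserves geometry and classification", {
  untr <- generate_facs_sample(n = 2000, positive_fraction = 0, seed = 12)
  gate <- build_mtkeima_gate(untr$sample, 99.8)
  path <- withr::local_tempfile(fileext = ".json")
  write_gate_json(gate, path)
  back <- read_gate_json(path)
  expect_equal(back$vertices, gate$vertices, ignore_attr = TRUE)
  smp <- generate_facs_sample(n = 2000, positive_fraction = 30, seed = 13)$sample
  expect_equal(percent_positive(smp, back), percent_positive(smp, gate))
})

test_that("pre-gating keeps double-positive events only", {
  gen <- generate_facs_sample(n = 1000, positive_fraction = 0, seed = 14)
  smp <- gen$sample
  smp$gfp[1:100] <- 0
  out <- pregate_double_positive(facs_sample(smp), gfp_min = 1)
  expect_identical(nrow(out), 900L)
})
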