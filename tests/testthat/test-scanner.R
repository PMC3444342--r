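test_that("scan reproduces the per-window worked example and anchor conventions", {
  tr <- scan("AAACCC", scan_config(window = 3, anchor = "start"))
  expect_equal(tr$positions, c(0, 1, 2, 3))
  expect_equal(tr$values, c(0, 2, 2, 0))

  ctr <- scan("AAACCC", scan_config(window = 3, anchor = "center"))
  expect_equal(ctr$positions, c(1, 2, 3, 4))
  expect_equal(ctr$values, tr$values)
})

test_that("scan validates geometry and degenerate inputs", {
  expect_equal(length(scan(random_dna(351, seed = 1))$values), 1L)  # L == window
  expect_error(scan("ACG", scan_config(window = 351)), "351",
               class = "period3_input_error")
  expect_error(scan_config(window = 4, anchor = "center"), "odd",
               class = "period3_input_error")
  expect_error(scan_config(window = 2), class = "period3_input_error")
  expect_error(scan_config(step = 0), class = "period3_input_error")
})

test_that("window count law holds over an exhaustive small grid", {
  full <- random_dna(60, seed = 2)
  for (w in c(3L, 9L, 21L)) {
    for (s in c(1L, 2L, 3L)) {
      for (L in seq(w, 60L)) {
        tr <- scan(substr(full, 1, L), scan_config(window = w, step = s))
        expect_length(tr$values, (L - w) %/% s + 1L)
        expect_equal(diff(tr$positions), rep(s, length(tr$positions) - 1L))
      }
    }
  }
})

test_that("appending residues never changes previously computable windows", {
  base <- random_dna(120, seed = 3)
  cfg <- scan_config(window = 21)
  short <- scan(base, cfg)
  long <- scan(paste0(base, random_dna(30)), cfg)
  expect_identical(long$values[seq_along(short$values)], short$values)
})

test_that("plan_chunks partitions window starts with the documented overlap", {
  cfg <- scan_config(window = 3, anchor = "start")
  plan <- plan_chunks(10, cfg, chunk_windows = 4)
  expect_equal(plan$chunks$first, c(0, 4))
  expect_equal(plan$chunks$last, c(3, 7))
  expect_equal(plan$chunks$start_bp, c(0, 4))
  expect_equal(plan$chunks$end_bp, c(6, 10))
  expect_equal(plan$overlap_bp, 2)

  # coverage: union of [first, last] ranges is every window index exactly once
  idx <- unlist(mapply(seq, plan$chunks$first, plan$chunks$last, SIMPLIFY = FALSE))
  expect_equal(idx, 0:7)

  single <- plan_chunks(10, cfg, chunk_windows = 100)
  expect_equal(nrow(single$chunks), 1L)
  one <- plan_chunks(3, cfg, chunk_windows = 5)
  expect_equal(one$chunks$first, 0)
  expect_equal(one$chunks$last, 0)
})

test_that("chunk coverage is a disjoint partition across random geometries", {
  set.seed(20)
  for (i in 1:25) {
    w <- sample(c(3L, 9L, 21L), 1)
    s <- sample(1:3, 1)
    L <- w + sample(0:80, 1)
    cw <- sample(1:10, 1)
    plan <- plan_chunks(L, scan_config(window = w, step = s, anchor = "start"), cw)
    idx <- unlist(mapply(seq, plan$chunks$first, plan$chunks$last, SIMPLIFY = FALSE))
    expect_equal(idx, seq(0L, (L - w) %/% s))
    expect_equal(plan$overlap_bp, w - s)
  }
})

test_that("scan_parallel equals scan for all worker/chunk combinations", {
  expect_equal(scan_parallel("AAACCC", scan_config(window = 3, anchor = "start"),
                             workers = 2, chunk_windows = 2)$values,
               c(0, 2, 2, 0))
  seq5k <- random_dna(5000, seed = 21)
  serial <- scan(seq5k)
  for (workers in c(1L, 2L, 4L)) {
    for (cw in c(100L, 1000L)) {
      par <- scan_parallel(seq5k, workers = workers, chunk_windows = cw)
      expect_identical(par$values, serial$values)
      expect_identical(par$positions, serial$positions)
    }
  }
})

test_that("fft backend scan matches goertzel backend scan", {
  s <- random_dna(800, seed = 22)
  g <- scan(s, scan_config(window = 351, backend = "goertzel"))
  f <- scan(s, scan_config(window = 351, backend = "fft"))
  expect_equal(f$values, g$values, tolerance = 1e-6)
  fp <- scan_parallel(s, scan_config(window = 351, backend = "fft"),
                      workers = 2, chunk_windows = 100)
  expect_equal(fp$values, g$values, tolerance = 1e-6)
})

test_that("max_parallel_instances applies the two-sided resource bound", {
  pu_only <- resource_budget(pu_total = 100, pu_fft = 10, pu_misc = 10,
                             mem_total = 1e12, mem_fft = 1, mem_misc = 1, mem_setup = 1)
  expect_identical(max_parallel_instances(pu_only), 2L)

  mem_only <- resource_budget(pu_total = 1e12, pu_fft = 1, pu_misc = 1,
                              mem_total = 100, mem_fft = 10, mem_misc = 5, mem_setup = 5)
  expect_identical(max_parallel_instances(mem_only), 2L)

  both <- resource_budget(pu_total = 336, pu_fft = 10, pu_misc = 2,
                          mem_total = 1024, mem_fft = 60, mem_misc = 8, mem_setup = 8)
  expect_identical(max_parallel_instances(both),
                   as.integer(min(floor(336 / 42), floor(1024 / 256))))

  expect_error(resource_budget(0, 1, 1, 1, 1, 1, 1), class = "period3_input_error")
})
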