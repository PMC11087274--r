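test_that("the cosine cutoff has the documented endpoints and monotonicity", {
  expect_equal(cutoff_fn(0, 5.2), 1)
  expect_equal(cutoff_fn(5.2, 5.2), 0)
  expect_equal(cutoff_fn(6.0, 5.2), 0)
  expect_equal(cutoff_fn(2.6, 5.2), 0.5, tolerance = 1e-12)
  r <- seq(0, 5.2, by = 0.01)
  expect_true(all(diff(cutoff_fn(r, 5.2)) <= 1e-12))
})

test_that("environment vectors are invariant to rotation and permutation", {
  set.seed(6)
  p <- descriptor_params()
  cfg <- random_safe_box(18, 20, min_r = 1.0)
  cfg <- configuration(cfg$species, cfg$positions, cell(60, periodic = FALSE),
                       wrap = FALSE)
  X <- environment_matrix(cfg, p)
  # rigid rotation about a random axis
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                2 * (q[2] * q[4] + q[1] * q[3]),
                2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                2 * (q[3] * q[4] - q[1] * q[2]),
                2 * (q[2] * q[4] - q[1] * q[3]),
                2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
              3, 3, byrow = TRUE)
  rot <- configuration(cfg$species, cfg$positions %*% t(R),
                       cell(60, periodic = FALSE), wrap = FALSE)
  expect_lt(max(abs(environment_matrix(rot, p) - X)), 1e-10)
  # swapping two like atoms permutes rows only
  el <- names(which.max(table(cfg$species)))
  ids <- which(cfg$species == el)[1:2]
  perm <- cfg; perm$positions[ids, ] <- perm$positions[rev(ids), ]
  Xp <- environment_matrix(perm, p)
  expect_lt(max(abs(Xp[ids[1], ] - X[ids[2], ])), 1e-12)
  others <- setdiff(seq_len(18), ids)
  expect_lt(max(abs(Xp[others, ] - X[others, ])), 1e-12)
})

test_that("atoms beyond the radial cutoff do not touch the environment vector", {
  p <- descriptor_params()
  base <- configuration(c("C", "H", "O"),
                        rbind(c(10, 10, 10), c(11, 10, 10), c(10, 11.2, 10)),
                        cell(40, periodic = FALSE), wrap = FALSE)
  v <- environment_vector(base, 1, p)
  plus <- configuration(c(base$species, "N"),
                        rbind(base$positions, c(10 + p$radial_cutoff + 0.5, 10, 10)),
                        cell(40, periodic = FALSE), wrap = FALSE)
  expect_lt(max(abs(environment_vector(plus, 1, p) - v)), 1e-12)
})

test_that("the vector varies smoothly as an atom crosses the cutoff", {
  p <- descriptor_params()
  vals <- sapply(seq(p$radial_cutoff - 0.05, p$radial_cutoff + 0.05, by = 0.001),
                 function(r) {
    cfg <- configuration(c("C", "C"),
                         rbind(c(10, 10, 10), c(10 + r, 10, 10)),
                         cell(40, periodic = FALSE), wrap = FALSE)
    sum(abs(environment_vector(cfg, 1, p)))
  })
  expect_lt(max(abs(diff(vals))), 1e-3)
  expect_equal(vals[length(vals)], 0)
})

test_that("environment vectors are deterministic and length-stable", {
  set.seed(8)
  p <- descriptor_params(elements = c("C", "H"))
  cfg <- random_safe_box(12, 7, elements = c("C", "H"))
  a <- environment_matrix(cfg, p)
  b <- environment_matrix(cfg, p)
  expect_identical(a, b)
  expect_equal(ncol(a), p$length)
  expect_error(descriptor_params(radial_cutoff = 3, angular_cutoff = 4),
               "angular_cutoff")
})
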