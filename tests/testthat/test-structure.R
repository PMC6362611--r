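test_that("structures concatenate component slabs with solvation", {
  s <- structure_model(slab(0, 1, name = "front"),
                       slab(50, 3, rough = 4, name = "layer"),
                       slab(0, 6.36, rough = 2, name = "back"))
  tab <- slabs_of(s)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$sld, c(1, 3, 6.36))
  expect_equal(tab$thick[2], 50)
  expect_equal(tab$rough, c(0, 4, 2))

  # full solvation: the slab takes the solvent SLD (default = backing)
  s2 <- structure_model(slab(0, 1), slab(50, 3, vfsolv = 1),
                        slab(0, 6.36))
  expect_equal(slabs_of(s2)$sld[2], 6.36)
  # partial solvation mixes linearly
  s3 <- structure_model(slab(0, 1), slab(50, 2, vfsolv = 0.3),
                        slab(0, 6.36))
  expect_equal(slabs_of(s3)$sld[2], 0.7 * 2 + 0.3 * 6.36)
  # explicit solvent overrides the backing default
  s4 <- structure_model(slab(0, 1), slab(50, 2, vfsolv = 0.5),
                        slab(0, 6.36), solvent = material(0))
  expect_equal(slabs_of(s4)$sld[2], 1)
  # fronting/backing rows are never solvated
  s5 <- structure_model(slab(0, 1, vfsolv = 1), slab(50, 2),
                        slab(0, 6.36))
  expect_equal(slabs_of(s5)$sld[1], 1)
  expect_error(slabs_of(structure_model(slab(0, 1))), "at least 2")
})

test_that("lipid leaflet SLDs follow area-per-molecule volume mixing", {
  solv <- material(6.36)
  # no solvent in the head region when V_h == A * t_h: SLD = b_h / V_h
  apm <- 319 / 9 # makes A * t_h == V_h exactly
  lf <- lipid_leaflet(apm, 6.01e-4, 319, 9, -2.92e-4, 782, 14, 3, 2)
  rows <- slabs:::component_slabs(lf, solv)
  expect_equal(rows$sld[1], 1e6 * 6.01e-4 / 319, tolerance = 1e-12)
  expect_equal(rows$thick, c(9, 14))
  expect_equal(rows$rough, c(2, 3)) # preceding first, head-tail second

  # b_t = 0 and half-filled tails in SLD-6 solvent give SLD 3
  apm2 <- 40
  v_t <- apm2 * 14 / 2
  lf2 <- lipid_leaflet(apm2, 6.01e-4, 319, 9, 0, v_t, 14, 3, 2,
                       tail_solvent = material(6))
  rows2 <- slabs:::component_slabs(lf2, solv)
  expect_equal(rows2$sld[2], 3, tolerance = 1e-12)

  # reversing swaps the row order but leaves both SLDs unchanged
  lf3 <- lipid_leaflet(60, 6.01e-4, 319, 9, -2.92e-4, 782, 14, 3, 2,
                       reverse = TRUE)
  lf4 <- lipid_leaflet(60, 6.01e-4, 319, 9, -2.92e-4, 782, 14, 3, 2)
  r3 <- slabs:::component_slabs(lf3, solv)
  r4 <- slabs:::component_slabs(lf4, solv)
  expect_equal(r3$sld, rev(r4$sld))
  expect_equal(r3$thick, rev(r4$thick))
  # the roughness pairing stays (preceding, internal)
  expect_equal(r3$rough, c(2, 3))

  # unphysical packing (V_x > A * t_x) is flagged via the prior, not clipped
  lf_bad <- lipid_leaflet(20, 6.01e-4, 319, 9, -2.92e-4, 782, 14, 3, 2)
  expect_identical(slabs:::component_log_prior(lf_bad), -Inf)
  expect_identical(slabs:::component_log_prior(lf4), 0)
})

test_that("a leaflet with identical head/tail composition acts as one slab", {
  # head and tail regions with the same SLD are indistinguishable from a
  # single uniform slab of the summed thickness
  apm <- 50
  b <- 4e-4; th <- 10; tt <- 12
  v_h <- apm * th; v_t <- apm * tt # fully packed: no solvent anywhere
  b_t <- b * tt / th # same b/(A t) in both regions
  lf <- lipid_leaflet(apm, b, v_h, th, b_t, v_t, tt,
                      rough_head_tail = 0, rough_preceding = 3)
  sld_regions <- 1e6 * b / (apm * th)
  s_lf <- structure_model(slab(0, 0), lf, slab(0, 6.36, rough = 4))
  s_slab <- structure_model(slab(0, 0),
                            slab(th + tt, sld_regions, rough = 3),
                            slab(0, 6.36, rough = 4))
  q <- seq(0.01, 0.3, by = 0.005)
  expect_equal(reflectivity(slabs_of(s_lf), q),
               reflectivity(slabs_of(s_slab), q), tolerance = 1e-12)
})

test_that("spline components discretise a shape-preserving interpolant", {
  # constant knots give constant slices
  sp <- sld_spline(c(0, 30), c(4, 4), m = 10)
  rows <- slabs:::component_slabs(sp, material(0))
  expect_equal(rows$sld, rep(4, 10))
  expect_equal(sum(rows$thick), 30)
  # linear knots give slice SLDs linear in the midpoint position
  sp2 <- sld_spline(c(0, 10, 20), c(1, 2, 3), m = 20)
  rows2 <- slabs:::component_slabs(sp2, material(0))
  mid <- cumsum(rows2$thick) - rows2$thick / 2
  expect_equal(rows2$sld, 1 + mid / 10, tolerance = 1e-9)
  expect_error(sld_spline(c(0, 10, 5), c(1, 2, 3)), "increasing")
  # refining the slicing converges: the change from doubling m shrinks,
  # and at moderate Q the discretisation error is at the 1e-4 level
  build <- function(m) {
    structure_model(slab(0, 0),
                    sld_spline(c(0, 20, 45, 60), c(1.5, 5, 2.5, 4), m = m),
                    slab(0, 6.36, rough = 3))
  }
  q <- seq(0.01, 0.1, by = 0.005)
  err <- vapply(c(100, 200, 400), function(m) {
    r1 <- reflectivity(slabs_of(build(m)), q)
    r2 <- reflectivity(slabs_of(build(2 * m)), q)
    max(abs(r2 - r1) / r1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-4)
})

test_that("model curves apply scale, background, mixing and smearing", {
  s <- simple_structure()
  q <- default_q_grid(60)
  base <- reflectivity(slabs_of(s), q)
  # scale 1 / background 0 / no smearing is the bare kernel
  m0 <- reflect_model(s, resolution = res_none())
  expect_identical(model_curve(m0, q), base)
  # scale and background act affinely
  m1 <- reflect_model(s, scale = 0.9, bkg = 1e-7, resolution = res_none())
  expect_equal(model_curve(m1, q), 0.9 * base + 1e-7)
  # the background floors the high-Q tail
  tail <- model_curve(m1, 0.5)
  expect_gt(tail, 1e-7)
  expect_lt(tail, 1.2e-7)
  # a 50/50 mixture of identical structures is the single-structure model
  mm <- mixed_reflect_model(list(s, s), fractions = c(0.5, 0.5),
                            resolution = res_none())
  expect_equal(model_curve(mm, q), base, tolerance = 1e-12)
  # pointwise resolution requires dq
  mp <- reflect_model(s, resolution = res_pointwise())
  expect_error(model_curve(mp, q), "per-point dQ")
  expect_silent(model_curve(mp, q, dq = 0.05 * q))
})

test_that("assembled structures and raw slab tables give equal kernels", {
  s <- structure_model(slab(0, 0.5), slab(80, 4.2, rough = 5),
                       slab(0, 6.1, rough = 3))
  tab <- slab_table(thick = c(0, 80, 0), sld = c(0.5, 4.2, 6.1),
                    rough = c(0, 5, 3))
  q <- seq(0.01, 0.3, by = 0.01)
  expect_identical(reflectivity(slabs_of(s), q), reflectivity(tab, q))
})

test_that("reversal symmetry holds for equal fronting and backing media", {
  # |r|^2 is invariant under flipping a lossless stack upside down when the
  # two semi-infinite media are identical. Reversing moves each roughness
  # with its interface.
  reverse_table <- function(tab) {
    m <- nrow(tab)
    slab_table(thick = rev(tab$thick), sld = rev(tab$sld),
               rough = c(0, rev(tab$rough[-1])))
  }
  q <- seq(0.01, 0.3, by = 0.005)
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(1:5, 1)
    med <- runif(1, 0, 2)
    tab <- slab_table(thick = c(0, runif(n, 5, 150), 0),
                      sld = c(med, runif(n, -1, 8), med),
                      rough = c(0, runif(n + 1, 0, 6)))
    expect_equal(reflectivity(reverse_table(tab), q),
                 reflectivity(tab, q), tolerance = 1e-9)
  }
})

test_that("SLD profiles join slabs by erf transitions of width sigma", {
  # zero roughness: step profile at the cumulative thicknesses
  s <- structure_model(slab(0, 1), slab(50, 3, rough = 0),
                       slab(0, 6, rough = 0))
  prof <- sld_profile(s, z = c(-10, 10, 49.9, 50.1, 200))
  expect_equal(prof$sld, c(1, 3, 3, 6, 6))
  # single rough interface: exactly the normal CDF form
  s2 <- structure_model(slab(0, 1), slab(0, 6, rough = 5))
  z <- seq(-25, 25, by = 0.5)
  prof2 <- sld_profile(s2, z = z)
  expect_equal(prof2$sld, 1 + (6 - 1) * pnorm(z / 5), tolerance = 1e-12)
  # far into the backing the profile reaches the backing SLD
  expect_equal(sld_profile(s2, z = 1e4)$sld, 6)
})
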