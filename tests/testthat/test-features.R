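tri345 <- rbind(c(0, 0), c(3, 0), c(3, 4))

test_that("area features reproduce textbook geometry", {
  expect_equal(sacc(tri345), 25 * pi / 4)
  expect_equal(sact(tri345), 6)
  expect_equal(sttc(tri345), pi)            # 3-4-5 incircle radius 1
  expect_equal(satcc(rbind(c(1, 0), c(0, 1))), 0.5)

  coll <- cbind(seq(0, 3, by = 0.5), seq(0, 6, by = 1))
  expect_equal(sact(coll), 0)
  expect_equal(sttc(coll), 0)

  expect_error(area_features(tri345), "at least 5")
  expect_error(sattc(tri345), "at least 5")
})

test_that("distortion features reproduce textbook geometry", {
  expect_equal(sac(rbind(c(0, 0), c(1, 0), c(1, 1))), 90)
  coll4 <- cbind(0:3, 0)
  expect_equal(sac(coll4), 0)
  expect_equal(sdcp(coll4), 3)

  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(bc(square), 4)               # perimeter 4, area 1
  expect_warning(val <- bc(coll4), "degenerate")
  expect_identical(val, Inf)

  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  circ <- cbind(2 * cos(th), 2 * sin(th))
  expect_equal(acu(circ), 0.5, tolerance = 1e-9)  # curvature 1/R

  # as-printed curvature: 2/(|u||v|), zero for collinear
  two_seg <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(acu(two_seg, mode = "as_printed"), 2)
  expect_equal(acu(coll4, mode = "as_printed"), 0)
})

test_that("center features reproduce closed-form cases", {
  online <- cbind(c(1, 2, -1), c(1, 2, -1))  # y = x
  cf <- center_features(online)
  expect_equal(cf[["SD45"]], 0)
  expect_equal(cf[["SP"]], 0)

  single <- center_features(matrix(c(3, 4), 1))
  expect_equal(single[["SDCO"]], 5)
  expect_equal(single[["DGCO"]], 5)

  cf2 <- center_features(rbind(c(1, 0), c(0, 5), c(-2, 0)))
  expect_equal(cf2[["DBNF"]], sqrt(26))

  sym <- rbind(c(2, 1), c(-2, -1), c(0.5, -3), c(-0.5, 3))
  expect_equal(center_features(sym)[["DGCO"]], 0)
})

test_that("every feature matches the direct-summation oracle", {
  set.seed(31)
  for (rep in 1:40) {
    xy <- random_trajectory(sample(6:60, 1), scale = runif(1, 0.1, 10))
    got <- topo_features(xy)
    want <- oracle_topo(xy)
    expect_equal(got, want[names(got)], tolerance = 1e-9)
  }
})

test_that("features obey the similarity-transform laws", {
  set.seed(32)
  xy <- random_trajectory(30)
  f <- topo_features(xy)
  cvals <- c(0.2, 3.7)
  for (cc in cvals) {
    fc <- topo_features(xy * cc)
    lengths <- c("SDCP", "SDTTC", "SDCO", "SD45", "SD135", "DBNF", "DGCO")
    areas <- c("SACC", "SACT", "STTC", "SATCC", "SP")
    angles <- c("SAC", "SATTC")
    expect_equal(fc[lengths], cc * f[lengths], tolerance = 1e-8)
    expect_equal(fc[areas], cc^2 * f[areas], tolerance = 1e-8)
    expect_equal(fc[angles], f[angles], tolerance = 1e-8)
    expect_equal(fc[["ACU"]], f[["ACU"]] / cc, tolerance = 1e-8)
    expect_equal(fc[["BC"]], f[["BC"]] / cc, tolerance = 1e-8)
  }
})

test_that("rotations about the origin preserve the rotation-invariant set", {
  set.seed(33)
  xy <- random_trajectory(25)
  f <- topo_features(xy)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  fr <- topo_features(xy %*% t(R))
  inv <- c("SDCO", "DBNF", "DGCO", "SACC", "SACT", "STTC", "SDTTC",
           "SAC", "BC", "ACU", "SDCP", "SATTC", "SATCC")
  expect_equal(fr[inv], f[inv], tolerance = 1e-8)
})

test_that("bisector reflections preserve the bisector-referenced features", {
  set.seed(34)
  xy <- random_trajectory(25)
  f <- topo_features(xy)
  # reflection across the 45-degree line swaps coordinates
  f45 <- topo_features(xy[, 2:1])
  # reflection across the 135-degree line: (x, y) -> (-y, -x)
  f135 <- topo_features(cbind(-xy[, 2], -xy[, 1]))
  for (ff in list(f45, f135))
    expect_equal(ff[c("SD45", "SD135", "SP")], f[c("SD45", "SD135", "SP")],
                 tolerance = 1e-8)
})

test_that("axis sign flips preserve all features except the bisector pair", {
  # flipping one embedding axis is a reflection across a coordinate axis:
  # lengths, areas, unsigned angles, hulls and origin distances survive,
  # while the two bisector-referenced sums trade places (and SP, their
  # symmetric product, is unchanged)
  set.seed(35)
  xy <- random_trajectory(30)
  f <- topo_features(xy)
  stable <- setdiff(names(f), c("SD45", "SD135"))
  for (flip in list(cbind(-xy[, 1], xy[, 2]), cbind(xy[, 1], -xy[, 2]))) {
    ff <- topo_features(flip)
    expect_equal(ff[stable], f[stable], tolerance = 1e-9)
    expect_equal(ff[["SD45"]], f[["SD135"]], tolerance = 1e-9)
    expect_equal(ff[["SD135"]], f[["SD45"]], tolerance = 1e-9)
  }
})

test_that("feature extraction yields one finite row per channel", {
  set.seed(36)
  ds <- generate_dataset(synth_config(n_subjects = 1, n_trials = 1,
                                      duration = 9, n_channels = 2,
                                      classes = c("neutral", "happy")))
  win <- segment_windows(ds$recordings[[1]])[[1]]
  fv <- extract_feature_vector(win, with_de = TRUE)
  expect_equal(nrow(fv), 2L)
  featcols <- topo_feature_names()
  expect_true(all(is.finite(as.matrix(fv[, featcols]))))
  expect_true(all(paste0("de_", names(default_bands())) %in% names(fv)))
  # centroid-at-origin is a structural consequence of the embedding
  expect_lt(max(fv$DGCO), 1e-6)

  # identical channels give identical features
  rec <- ds$recordings[[1]]
  rec$data[, 2] <- rec$data[, 1]
  fv2 <- extract_feature_vector(segment_windows(rec)[[1]])
  expect_equal(unname(as.matrix(fv2[1, featcols])),
               unname(as.matrix(fv2[2, featcols])))

  expect_error(extract_feature_vector(win, channels = "Oz"), "unknown")
})
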