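test_that("label map partitions the lattice and measures a straight border", {
  # rectangle split by a vertical line: border length ~ rectangle height
  b <- boundary_curve(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)), "rect")
  lat <- build_lattice(b, 0.04)
  H <- lat$n_hex
  cmat <- matrix(0, H, 2L)
  left <- lat$centres[, 1L] < 1
  cmat[cbind(seq_len(H), ifelse(left, 1L, 2L))] <- 1
  lm <- label_map(cmat, lat, labels = c("L", "R"))
  expect_equal(sum(lm$areas), H * lat$omega)
  expect_equal(unname(lm$V["L", "R"]), unname(lm$V["R", "L"]))
  # zig-zag border along a hex column: length within ~20% of the height
  expect_gt(lm$V["L", "R"], 0.9)
  expect_lt(lm$V["L", "R"], 1.35)
  expect_true(all(diag(lm$V) == 0))
  # V entries are multiples of the hex edge length
  mult <- lm$V / lat$edge_len
  expect_equal(mult, round(mult), tolerance = 1e-9)
  expect_true(all(rowSums(lm$V) <= lm$b + 1e-12))

  # ties go to the lowest projection index
  tie <- matrix(0.5, H, 2L)
  expect_true(all(label_map(tie, lat)$label == 1L))
  # zero connections fall back to the branching argmax
  amat <- matrix(runif(2 * H), H, 2L)
  lm2 <- label_map(matrix(0, H, 2L), lat, a = amat)
  expect_equal(lm2$label, max.col(amat, ties.method = "first"))
})

test_that("single occupied projection owns the whole domain", {
  lat <- fix_ellipse$lattice
  H <- lat$n_hex
  cmat <- cbind(rep(0.2, H), rep(0.05, H))
  lm <- label_map(cmat, lat, labels = c("win", "lose"))
  expect_equal(unname(lm$areas["win"]), H * lat$omega)
  expect_equal(unname(lm$areas["lose"]), 0)
  expect_error(honda_delta(lm, lat), "2 regions")
})

test_that("Honda delta is near zero for Voronoi maps and grows with distortion", {
  lat <- build_lattice(make_ellipse_boundary(2, 1, 128), 0.04)
  set.seed(7)
  th <- runif(6, 0, 2 * pi)
  rr <- sqrt(runif(6, 0.1, 0.8))
  pts <- cbind(2 * rr * cos(th), rr * sin(th))
  rownames(pts) <- paste0("R", 1:6)
  ref <- make_reference_labelmap(pts, lat)
  d0 <- honda_delta(ref, lat)
  expect_lt(d0, 0.02)
  # displacing an internal border strictly and monotonically increases delta
  deltas <- vapply(c(0.08, 0.2), function(shift) {
    lab <- ref$label
    i <- ref$label[which.max(lat$centres[, 1L])]  # a region at the +x end
    # grow region i by `shift` mm: every hex within shift of it flips
    mine <- lab == i
    d2 <- sqrt(outer(lat$centres[, 1L], lat$centres[mine, 1L], "-")^2 +
               outer(lat$centres[, 2L], lat$centres[mine, 2L], "-")^2)
    grab <- apply(d2, 1L, min) < shift
    lab[grab] <- i
    lm <- label_map_from_labels(lab, 6L, ref$labels, lat)
    honda_delta(lm, lat)
  }, numeric(1L))
  expect_gt(deltas[1L], d0)
  expect_gt(deltas[2L], deltas[1L])
})

test_that("Honda delta is invariant under rigid motion of the map", {
  lat <- build_lattice(make_ellipse_boundary(1.5, 0.8, 128), 0.05)
  set.seed(12)
  th <- runif(5, 0, 2 * pi)
  rr <- sqrt(runif(5, 0.1, 0.8))
  pts <- cbind(1.5 * rr * cos(th), 0.8 * rr * sin(th))
  ref <- make_reference_labelmap(pts, lat)
  d0 <- honda_delta(ref, lat)
  # rotate + translate every centre; combinatorics unchanged
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  lat2 <- lat
  lat2$centres <- sweep(lat$centres %*% t(R), 2L, c(3, -1), "+")
  ref2 <- ref
  ref2$centroids <- sweep(ref$centroids %*% t(R), 2L, c(3, -1), "+")
  # small absolute slack: the generator box constraints are axis-aligned,
  # so the optimization path is not exactly rotation-invariant
  expect_lt(abs(honda_delta(ref2, lat2) - d0), 0.005)
})

test_that("pattern difference is zero on identity, symmetric, and scales as length^3", {
  lat <- fix_ellipse$lattice
  set.seed(21)
  pts <- cbind(runif(5, -0.7, 0.7), runif(5, -0.35, 0.35))
  rownames(pts) <- paste0("R", 1:5)
  m1 <- make_reference_labelmap(pts, lat)
  expect_equal(pattern_difference(m1, m1), 0)
  pts2 <- pts + matrix(rnorm(10, 0, 0.08), 5L)
  m2 <- make_reference_labelmap(pts2, lat)
  eta <- pattern_difference(m1, m2)
  expect_gt(eta, 0)
  expect_equal(pattern_difference(m2, m1), eta)

  # build the geometrically scaled twin lattice: same hex set, lambda x size
  lambda <- 2.5
  blam <- make_ellipse_boundary(1.0 * lambda, 0.5 * lambda, 128)
  latlam <- build_lattice(blam, 0.06 * lambda)
  expect_equal(latlam$n_hex, lat$n_hex)
  expect_equal(latlam$centres, lat$centres * lambda, tolerance = 1e-9)
  m1l <- label_map_from_labels(m1$label, 5L, m1$labels, latlam)
  m2l <- label_map_from_labels(m2$label, 5L, m2$labels, latlam)
  expect_equal(pattern_difference(m1l, m2l), eta * lambda^3, tolerance = 1e-9)
})

test_that("pattern difference handles absent regions and disjoint adjacency", {
  lat <- fix_ellipse$lattice
  set.seed(2)
  pts <- cbind(runif(4, -0.6, 0.6), runif(4, -0.3, 0.3))
  rownames(pts) <- paste0("R", 1:4)
  ref <- make_reference_labelmap(pts, lat)
  # sim in which region R4 never wins
  lab <- ref$label
  lab[lab == 4L] <- 1L
  sim <- label_map_from_labels(lab, 4L, ref$labels, lat)
  eta <- pattern_difference(sim, ref)
  expect_true(is.finite(eta) && eta > 0)
  expect_error(pattern_difference(
    label_map_from_labels(rep(1L, lat$n_hex), 2L, c("A", "B"), lat), ref),
    "label sets")
})

test_that("selectivity has the stated bounds and sharpening monotonicity", {
  lat <- fix_ellipse$lattice
  H <- lat$n_hex
  N <- 6L
  area <- H * lat$omega
  even <- matrix(0.1, H, N)
  s <- selectivity(even, lat)
  expect_equal(s$mu, rep(1 / N, H))
  expect_equal(s$omega, area / N)
  dom <- matrix(0, H, N)
  dom[, 3L] <- 0.4
  expect_equal(selectivity(dom, lat)$omega, area)
  # zero state: no-information convention mu = 1/N
  expect_equal(selectivity(matrix(0, H, N), lat)$omega, area / N)
  set.seed(8)
  cmat <- matrix(runif(H * N), H, N)
  s1 <- selectivity(cmat, lat)
  expect_true(all(s1$mu >= 1 / N - 1e-12 & s1$mu <= 1 + 1e-12))
  expect_true(s1$omega >= area / N && s1$omega <= area)
  # raising densities to a power > 1 sharpens: mu cannot decrease anywhere
  s2 <- selectivity(cmat^3, lat)
  expect_true(all(s2$mu >= s1$mu - 1e-12))
  expect_gte(s2$omega, s1$omega)
})

test_that("metric and label-map exports round-trip through CSV", {
  lat <- fix_ellipse$lattice
  met <- data.frame(step = c(1000L, 2000L), delta = c(0.2, 0.1),
                    eta = c(3.5, 1.2), omega = c(0.3, 0.5))
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(met, f)
  expect_equal(read.csv(f), met)
  set.seed(1)
  pts <- cbind(runif(3, -0.5, 0.5), runif(3, -0.3, 0.3))
  rownames(pts) <- c("A1", "B2", "C3")
  lm <- make_reference_labelmap(pts, lat)
  fl <- tempfile(fileext = ".csv")
  write_labelmap_csv(lm, fl)
  df <- read.csv(fl)
  expect_equal(df$label, lm$labels[lm$label])
  fs <- tempfile(fileext = ".svg")
  write_labelmap_svg(lm, lat, fs)
  expect_true(file.exists(fs) && file.size(fs) > 1000)
})
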