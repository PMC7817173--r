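test_that("Delaunay edges satisfy classical structural identities", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    ed <- delaunay_edges(x, y)
    # Euler: a triangulated point set has 3n - 3 - h edges (h hull points)
    h <- length(grDevices::chull(x, y))
    expect_equal(nrow(ed), 3 * n - 3 - h)
    # each point's nearest neighbor is always a Delaunay neighbor
    keys <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    for (i in seq_len(n)) {
      d <- sqrt((x - x[i])^2 + (y - y[i])^2)
      d[i] <- Inf
      j <- which.min(d)
      expect_true(paste(min(i, j), max(i, j)) %in% keys)
    }
  }
})

test_that("neighbor graph prunes long edges and matches brute force", {
  # two cells 5 um apart within a 15 um cutoff: one edge
  two <- data.frame(cell_id = c("a", "b"), x_um = c(0, 5), y_um = 0)
  g <- build_neighbor_graph(two)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$dist_um, 5)
  # unit hexagon + center: center has six neighbors
  hexc <- hex_disc_clone(1)
  gh <- build_neighbor_graph(hexc, max_neighbor_dist = 11)
  ctr <- which(hexc$x_um == 0 & hexc$y_um == 0)
  deg <- table(c(gh$edges$from, gh$edges$to))
  expect_equal(unname(deg[hexc$cell_id[ctr]]), 6L)
  # below 3 cells the graph is the plain threshold graph
  three <- data.frame(cell_id = c("a", "b", "c"), x_um = c(0, 5, 100),
                      y_um = c(0, 0, 0))
  gt <- build_neighbor_graph(three, max_neighbor_dist = 15)
  expect_equal(graph_edge_keys(gt), "a|b")  # collinear fallback
  # random sets: graph edges are exactly Delaunay edges within the cutoff
  for (seed in 4:5) {
    cells <- random_cells(40, seed)
    cells$layer <- "basal"
    g <- build_neighbor_graph(cells, max_neighbor_dist = 20)
    expect_true(all(g$edges$dist_um <= 20))
    expect_true(all(graph_edge_keys(g) %in% brute_force_pairs(cells, 20)))
  }
})

test_that("neighbor graph is permutation-invariant and handles duplicates", {
  cells <- random_cells(30, seed = 11)
  cells$layer <- "basal"
  g1 <- build_neighbor_graph(cells)
  set.seed(1)
  g2 <- build_neighbor_graph(cells[sample(nrow(cells)), ])
  expect_equal(graph_edge_keys(g1), graph_edge_keys(g2))
  dup <- cells
  dup$x_um[2] <- dup$x_um[1]; dup$y_um[2] <- dup$y_um[1]
  expect_warning(build_neighbor_graph(dup), "jitter")
  expect_error(build_neighbor_graph(dup, on_duplicates = "error"),
               "duplicate")
})

test_that("edge/inner classification is exact on canonical geometries", {
  # a lone cell is all edge
  lone <- data.frame(animal_id = "a", clone_id = "c1", cell_id = "x",
                     x_um = 0, y_um = 0, layer = "basal", genotype = "WT",
                     edu = 0, brdu = 0, k10 = 0)
  expect_equal(classify_edge_inner(lone, "c1")$role, "edge")
  # 7-cell rosette: 6 edge, 1 inner, in both modes
  ros_bg <- hex_disc_clone(1, wt_ring = 1)
  r1 <- classify_edge_inner(ros_bg, "clone1")
  expect_equal(sum(r1$role == "edge"), 6L)
  expect_equal(sum(r1$role == "inner"), 1L)
  ros <- hex_disc_clone(1)
  r2 <- classify_edge_inner(ros, "clone1", mode = "alpha_boundary")
  expect_equal(sum(r2$role == "edge"), 6L)
  expect_equal(sum(r2$role == "inner"), 1L)
  # radius-2 disc embedded in a wild-type ring: 12 boundary cells
  disc <- hex_disc_clone(2, wt_ring = 1)
  r3 <- classify_edge_inner(disc, "clone1")
  expect_equal(sum(r3$role == "edge"), 12L)
  expect_equal(sum(r3$role == "inner"), 7L)
  expect_error(classify_edge_inner(disc, "ghost"), "no basal cells")
})

test_that("edge labels match a brute-force neighbor scan on random blobs", {
  set.seed(21)
  for (rep in 1:3) {
    pts <- hex_disc(4)
    keep <- sample(nrow(pts), 25)
    cells <- data.frame(
      animal_id = "a",
      clone_id = ifelse(seq_along(keep) <= 15, "c1", NA),
      cell_id = sprintf("c%02d", seq_along(keep)),
      x_um = pts$x_um[keep], y_um = pts$y_um[keep],
      layer = "basal", genotype = "WT", edu = 0, brdu = 0, k10 = 0,
      stringsAsFactors = FALSE)
    g <- build_neighbor_graph(cells, max_neighbor_dist = 11)
    got <- classify_edge_inner(cells, "c1", graph = g)
    for (k in seq_len(nrow(got))) {
      i <- match(got$cell_id[k], cells$cell_id)
      nbr <- unique(c(g$edges$to[g$edges$from == cells$cell_id[i]],
                      g$edges$from[g$edges$to == cells$cell_id[i]]))
      outside <- cells$cell_id[is.na(cells$clone_id) |
                                 cells$clone_id != "c1"]
      want <- if (length(nbr) == 0 || any(nbr %in% outside)) "edge" else
        "inner"
      expect_equal(got$role[k], want)
    }
  }
})

test_that("removing background cells never converts inner to edge cells", {
  cells <- hex_disc_clone(2, wt_ring = 1)
  base <- classify_edge_inner(cells, "clone1")
  inner0 <- base$cell_id[base$role == "inner"]
  bg <- which(is.na(cells$clone_id))
  for (drop in bg[seq(1, length(bg), by = 3)]) {
    red <- classify_edge_inner(cells[-drop, ], "clone1")
    # former inner cells stay inner; edges may relax to inner, never the
    # other way
    expect_true(all(red$role[red$cell_id %in% inner0] == "inner"))
  }
})

test_that("ellipse fits recover closed-form geometry", {
  th <- seq(0, 2 * pi, length.out = 401)[-1]
  circ <- fit_ellipse(30 * cos(th), 30 * sin(th), input = "outline")
  expect_equal(circ$area_um2, pi * 900, tolerance = 0.01)
  expect_equal(circ$perimeter_um, 2 * pi * 30, tolerance = 0.01)
  # 2:1 ellipse perimeter against direct elliptic-integral quadrature
  a <- 40; b <- 20
  ell <- fit_ellipse(a * cos(th), b * sin(th), input = "outline")
  quad <- stats::integrate(function(t)
    sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2), 0, 2 * pi,
    rel.tol = 1e-10)$value
  expect_equal(ell$perimeter_um, quad, tolerance = 1e-3)
  expect_equal(ell$area_um2, pi * a * b, tolerance = 1e-3)
  # rotation invariance
  phi <- 0.83
  rot <- fit_ellipse(a * cos(th) * cos(phi) - b * sin(th) * sin(phi),
                     a * cos(th) * sin(phi) + b * sin(th) * cos(phi),
                     input = "outline")
  expect_equal(rot$area_um2, ell$area_um2, tolerance = 1e-9)
  expect_equal(rot$perimeter_um, ell$perimeter_um, tolerance = 1e-9)
  # centroid cloud of a filled disc recovers its area
  set.seed(5)
  rr <- 30 * sqrt(runif(3000)); tt <- runif(3000, 0, 2 * pi)
  disc <- fit_ellipse(rr * cos(tt), rr * sin(tt), input = "points")
  expect_equal(disc$area_um2, pi * 900, tolerance = 0.05)
  expect_error(fit_ellipse(c(0, 1, 2), c(0, 1, 2)), "degenerate|collinear")
})

test_that("circularity obeys the isoperimetric bound", {
  expect_equal(circularity(pi * 25, 2 * pi * 5), 1)
  expect_equal(circularity(100, 40), pi / 4, tolerance = 1e-12)
  # numerical noise past the bound is capped
  expect_equal(circularity(pi * 25 * 1.0001, 2 * pi * 5), 1)
  expect_error(circularity(-1, 10), "positive")
  set.seed(6)
  for (i in 1:10) {
    a <- runif(1, 10, 50); b <- runif(1, 5, a)
    e <- fit_ellipse(a * cos(seq(0.01, 2 * pi, length.out = 300)),
                     b * sin(seq(0.01, 2 * pi, length.out = 300)),
                     input = "outline")
    cc <- circularity(e$area_um2, e$perimeter_um)
    expect_gt(cc, 0)
    expect_lte(cc, 1)
  }
})

test_that("clone density is the basal count per unit area", {
  expect_equal(clone_density(10, 100), 0.1)
  expect_equal(clone_density(10, 200), 0.05)  # doubling area halves it
  expect_error(clone_density(0, 100), "at least 1")
  expect_error(clone_density(10, 0), "positive")
})

test_that("clone morphometrics compose consistently", {
  m <- clone_morphometrics(hex_disc_clone(2, wt_ring = 1), "clone1")
  expect_equal(m$n_basal, 19L)
  expect_equal(m$n_edge + m$n_inner, m$n_basal)
  expect_equal(m$edge_fraction, m$n_edge / m$n_basal)
  expect_equal(m$density_per_um2, m$n_basal / m$area_um2)
  expect_gt(m$circularity, 0.9)  # hexagonal discs are nearly round
})

test_that("timecourse shows shrinking edge fraction as clones grow", {
  weeks <- c(2, 4, 10, 24)
  radii <- c(1, 2, 4, 6)
  tabs <- do.call(rbind, lapply(seq_along(weeks), function(i) {
    tab <- hex_disc_clone(radii[i], wt_ring = 1)
    tab$week <- weeks[i]
    tab
  }))
  tc <- morphometry_timecourse(tabs)
  ef <- tc$per_clone$edge_fraction[order(tc$per_clone$week)]
  expect_true(all(diff(ef) < 0))
  # a clone replicated across weeks keeps identical metrics
  rep2 <- do.call(rbind, lapply(c(2, 4), function(w) {
    tab <- hex_disc_clone(3, wt_ring = 1); tab$week <- w; tab
  }))
  tcr <- morphometry_timecourse(rep2)
  expect_equal(tcr$per_clone$edge_fraction[1],
               tcr$per_clone$edge_fraction[2])
  expect_equal(tcr$per_clone$area_um2[1], tcr$per_clone$area_um2[2])
  # a week with no clones warns and is skipped
  empty_wk <- hex_disc_clone(1, wt_ring = 1)
  empty_wk$week <- 2
  empty_wk2 <- empty_wk
  empty_wk2$week <- 4
  empty_wk2$clone_id <- NA_character_
  expect_warning(morphometry_timecourse(rbind(empty_wk, empty_wk2)),
                 "no clones")
})
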