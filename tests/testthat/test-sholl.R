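swc_text <- function(...) {
  tf <- tempfile(fileext = ".swc")
  writeLines(c(...), tf)
  tf
}

test_that("SWC parsing validates roots, parents and cycles", {
  chain <- read_swc(swc_text(
    "# comment",
    "1 1 0 0 0 1 -1",
    "2 3 10 0 0 0.5 1",
    "3 3 20 0 0 0.5 2"
  ))
  expect_s3_class(chain, "swc_neuron")
  expect_equal(nrow(chain), 3)
  expect_equal(chain$id[chain$parent == -1], 1)

  expect_error(read_swc(swc_text("1 1 0 0 0 1 -1", "3 3 1 0 0 1 9")),
               "missing parent", class = "spinedyn_format_error")
  expect_error(read_swc(swc_text("1 1 0 0 0 1 -1", "2 1 1 1 1 1 -1")),
               "exactly one root", class = "spinedyn_format_error")
  expect_error(read_swc(swc_text("1 1 0 0 0 1 -1", "2 3 1 0 0 1 3",
                                 "3 3 2 0 0 1 2")),
               "cycle", class = "spinedyn_format_error")
})

test_that("generated trees round-trip through write/read", {
  tree <- generate_tree(n_primaries = 4, branch_prob = 0.4, seed = 12)
  tf <- tempfile(fileext = ".swc")
  write_swc(tree, tf)
  back <- read_swc(tf)
  expect_equal(back$id, tree$id)
  expect_equal(back$parent, tree$parent)
  expect_equal(back$x, tree$x, tolerance = 1e-7)
})

test_that("a single radial segment crosses each shell below its tip exactly once", {
  trace <- validate_swc(tibble::tibble(
    id = 1:2, type = c(1, 3), x = c(0, 95), y = 0, z = 0, radius = 1,
    parent = c(-1, 1)
  ))
  prof <- sholl_intersections(trace, shell_step = 10)
  expect_equal(prof$radius, seq(10, 100, 10))
  expect_equal(prof$intersections, c(rep(1L, 9), 0L))
})

test_that("a bifurcating trunk doubles its crossings beyond the branch point", {
  trace <- validate_swc(tibble::tibble(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(0, 30, 60, 30), y = c(0, 0, 0, sqrt(60^2 - 30^2)), z = 0,
    radius = 1, parent = c(-1, 1, 2, 2)
  ))
  # trunk to 30 um, bifurcating into two branches whose tips both lie
  # 60 um from the soma
  prof <- sholl_intersections(trace, shell_step = 10)
  expect_equal(prof$intersections[prof$radius == 10], 1L)
  expect_equal(prof$intersections[prof$radius == 20], 1L)
  expect_equal(prof$intersections[prof$radius == 40], 2L)
  expect_equal(prof$intersections[prof$radius == 50], 2L)
})

test_that("profiles match the dense-sampling oracle on random trees", {
  withr::local_seed(7)
  for (seed in 1:12) {
    tree <- generate_tree(n_primaries = sample(2:5, 1),
                          branch_prob = runif(1, 0.2, 0.6),
                          mean_segment_um = 12, seed = seed)
    for (mode in c("3d", "2d")) {
      prof <- sholl_intersections(tree, shell_step = 7, mode = mode)
      expect_equal(prof$intersections,
                   oracle_sholl(tree, prof$radius, mode = mode),
                   info = paste("seed", seed, mode))
    }
  }
})

test_that("profiles vanish beyond the arbor and double-dip chords count twice", {
  # chord passing near the soma: both endpoints outside r = 10, dips inside
  trace <- validate_swc(tibble::tibble(
    id = 1:3, type = c(1, 3, 3),
    x = c(0, -50, 50), y = c(0, 5, 5), z = 0, radius = 1,
    parent = c(-1, 1, 2)
  ))
  prof <- sholl_intersections(trace, shell_step = 10)
  # the chord from (-50,5) to (50,5) dips to 5 um from the soma and counts
  # twice; the root-to-(-50,5) segment adds one ordinary crossing
  expect_equal(prof$intersections[prof$radius == 10], 3L)
  expect_equal(prof$intersections[length(prof$intersections)], 0L)
  expect_true(max(prof$radius) >= max(sqrt(trace$x^2 + trace$y^2)))
})

test_that("3D and 2D profiles agree for planar traces and resist rigid motion", {
  tree <- generate_tree(n_primaries = 4, branch_prob = 0.5, seed = 3)
  flat <- tree
  flat$z <- 2.5
  p3 <- sholl_intersections(flat, shell_step = 8, mode = "3d")
  p2 <- sholl_intersections(flat, shell_step = 8, mode = "2d")
  expect_equal(p3$intersections, p2$intersections)

  # rigid rotation + translation leaves 3D profile and lengths unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(tree[, c("x", "y", "z")]) %*% rot
  moved <- tree
  moved$x <- xyz[, 1] + 12; moved$y <- xyz[, 2] - 4; moved$z <- xyz[, 3] + 1
  expect_equal(sholl_intersections(moved, 8)$intersections,
               sholl_intersections(tree, 8)$intersections)
  expect_equal(tree_lengths(moved)$total_length,
               tree_lengths(tree)$total_length, tolerance = 1e-6)
})

test_that("primary branch count is the root's child count", {
  tree0 <- generate_tree(n_primaries = 7, branch_prob = 0, seed = 5)
  expect_equal(primary_branch_count(tree0), 7)
  expect_equal(nrow(tree0), 8)  # straight primaries only

  chain <- validate_swc(tibble::tibble(
    id = 1:3, type = 1, x = c(0, 1, 2), y = 0, z = 0, radius = 1,
    parent = c(-1, 1, 2)
  ))
  expect_equal(primary_branch_count(chain), 1)

  tree <- generate_tree(n_primaries = 3, branch_prob = 0.6, seed = 8)
  expect_equal(primary_branch_count(tree), 3)
})

test_that("tree lengths: 3-4-5 segment, per-tree partition, generator bookkeeping", {
  seg <- validate_swc(tibble::tibble(
    id = 1:2, type = c(1, 3), x = c(0, 3), y = c(0, 4), z = 0, radius = 1,
    parent = c(-1, 1)
  ))
  tl <- tree_lengths(seg)
  expect_equal(tl$total_length, 5)
  expect_equal(tl$longest_tree_length, 5)

  # two primaries with summed lengths 40 and 60
  two <- validate_swc(tibble::tibble(
    id = 1:5, type = c(1, 3, 3, 3, 3),
    x = c(0, 10, 40, 0, 0), y = c(0, 0, 0, 25, 60), z = 0, radius = 1,
    parent = c(-1, 1, 2, 1, 4)
  ))
  tl2 <- tree_lengths(two)
  expect_equal(sort(tl2$trees$length), c(40, 60))
  expect_equal(tl2$total_length, 100)
  expect_equal(tl2$longest_tree_length, 60)

  for (seed in 1:5) {
    tree <- generate_tree(n_primaries = 3, branch_prob = 0.5, seed = seed)
    tl3 <- tree_lengths(tree)
    expect_equal(tl3$total_length, attr(tree, "total_length_true"),
                 tolerance = 1e-9)
    expect_equal(sum(tl3$trees$length), tl3$total_length)
    expect_equal(nrow(tl3$trees), 3)
  }
})

test_that("denser branching stochastically enlarges the Sholl profile area", {
  area <- function(branch_prob, seed) {
    tree <- generate_tree(n_primaries = 4, branch_prob = branch_prob,
                          max_order = 5, seed = seed)
    sum(sholl_intersections(tree, shell_step = 10)$intersections)
  }
  lo <- vapply(1:40, function(s) area(0.1, s), numeric(1))
  hi <- vapply(1:40, function(s) area(0.6, 1000 + s), numeric(1))
  expect_lt(stats::wilcox.test(hi, lo, alternative = "greater",
                               exact = FALSE)$p.value,
            0.01)
})
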