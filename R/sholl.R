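#' Read an SWC neurite/astrocyte trace
#'
#' Parses the standard 7-column SWC text format (node id, structure type,
#' x, y, z, radius, parent id; `#` comments allowed). The trace must have
#' exactly one root (parent `-1`), valid parent references and no cycles;
#' multi-point soma contours are not collapsed — the root node is the soma
#' centre.
#'
#' @param path Path to an SWC file.
#' @return An `swc_neuron` tibble with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("SWC file not found: ", path), class = "spinedyn_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("SWC file has no data lines", class = "spinedyn_format_error")
  }
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7)) {
    abort(paste0("SWC line ", which(lengths(fields) != 7)[1],
                 " does not have 7 fields"),
          class = "spinedyn_format_error")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  trace <- tibble::tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  validate_swc(trace)
}

#' Write an SWC trace
#'
#' @param trace An `swc_neuron` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  trace <- validate_swc(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d", trace$id, trace$type,
                     trace$x, trace$y, trace$z, trace$radius, trace$parent),
             con)
  invisible(path)
}

#' Validate an SWC node table
#'
#' Checks single-root, valid parent references, and connectivity from the
#' root (which also rules out cycles).
#'
#' @param trace A data frame with SWC columns.
#' @return The validated `swc_neuron` tibble.
#' @export
validate_swc <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(trace)))
  trace <- tibble::as_tibble(trace)
  trace$id <- as.integer(trace$id)
  trace$type <- as.integer(trace$type)
  trace$parent <- as.integer(trace$parent)
  if (anyDuplicated(trace$id)) {
    abort(paste0("duplicate SWC node id ",
                 trace$id[duplicated(trace$id)][1]),
          class = "spinedyn_format_error")
  }
  roots <- trace$id[trace$parent == -1]
  if (length(roots) != 1) {
    abort(paste0("SWC trace must have exactly one root, found ",
                 length(roots)),
          class = "spinedyn_format_error")
  }
  dangling <- setdiff(trace$parent, c(-1L, trace$id))
  if (length(dangling) > 0) {
    bad <- trace$id[trace$parent == dangling[1]][1]
    abort(paste0("node ", bad, " references missing parent ", dangling[1]),
          class = "spinedyn_format_error")
  }
  # connectivity / acyclicity: walk up from every node; must reach the root
  parent_of <- setNames(trace$parent, trace$id)
  n <- nrow(trace)
  for (start in trace$id) {
    cur <- start
    steps <- 0L
    while (cur != -1L) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) {
        abort(paste0("cycle detected at node ", start),
              class = "spinedyn_format_error")
      }
    }
  }
  class(trace) <- unique(c("swc_neuron", class(trace)))
  trace
}

# internal: segment table (one row per parent-child edge) with endpoint and
# closest-approach distances from the root, in 3D or the XY projection
swc_segments <- function(trace, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  root <- trace[trace$parent == -1, ]
  child <- trace[trace$parent != -1, ]
  idx <- match(child$parent, trace$id)
  p1 <- cbind(trace$x[idx], trace$y[idx], trace$z[idx])
  p2 <- cbind(child$x, child$y, child$z)
  centre <- c(root$x, root$y, root$z)
  if (mode == "2d") {
    p1[, 3] <- 0; p2[, 3] <- 0; centre[3] <- 0
  }
  d1 <- sqrt(rowSums((p1 - rep(centre, each = nrow(p1)))^2))
  d2 <- sqrt(rowSums((p2 - rep(centre, each = nrow(p2)))^2))
  v <- p2 - p1
  len2 <- rowSums(v^2)
  tt <- rowSums((rep(centre, each = nrow(p1)) - p1) * v) /
    ifelse(len2 == 0, 1, len2)
  tt <- pmin(pmax(tt, 0), 1)
  closest <- p1 + v * tt
  dmin <- sqrt(rowSums((closest - rep(centre, each = nrow(p1)))^2))
  tibble::tibble(
    child_id = child$id, d1 = d1, d2 = d2, dmin = dmin,
    length = sqrt(if (mode == "2d") rowSums(v[, 1:2, drop = FALSE]^2)
                  else len2)
  )
}

#' Sholl intersection profile
#'
#' Counts intersections of the arbor with concentric shells of radius
#' `k * shell_step` centred on the root (soma). In `"3d"` mode shells are
#' spheres; in `"2d"` mode the trace is projected onto the XY plane and
#' shells are circles. Each straight segment contributes 1 intersection to a
#' shell its endpoints straddle, 2 when both endpoints lie outside but the
#' segment's closest approach to the centre dips inside, and 0 otherwise.
#' The profile ends at the first radius beyond the arbor's maximal extent
#' (that final count is 0 by construction).
#'
#' @param trace An `swc_neuron` tibble.
#' @param shell_step Shell spacing in micrometres (> 0); default 10.
#' @param mode `"3d"` (default) or `"2d"` (XY projection).
#' @return A `sholl_profile` tibble: `radius` (µm), `intersections`, and the
#'   `shell_step` used.
#' @export
#' @examples
#' tree <- generate_tree(n_primaries = 5, branch_prob = 0.5, seed = 2)
#' sholl_intersections(tree, shell_step = 10)
sholl_intersections <- function(trace, shell_step = 10,
                                mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  trace <- validate_swc(trace)
  if (!is.finite(shell_step) || shell_step <= 0) {
    abort("shell_step must be > 0", class = "spinedyn_value_error")
  }
  if (nrow(trace) < 2) {
    abort("trace has no segments", class = "spinedyn_value_error")
  }
  seg <- swc_segments(trace, mode)
  max_extent <- max(seg$d1, seg$d2)
  k_max <- floor(max_extent / shell_step) + 1L
  radii <- shell_step * seq_len(k_max)
  counts <- vapply(radii, function(r) {
    straddle <- (seg$d1 < r) != (seg$d2 < r)
    dip <- seg$d1 > r & seg$d2 > r & seg$dmin < r
    sum(straddle) + 2L * sum(dip)
  }, numeric(1))
  out <- tibble::tibble(radius = radii, intersections = as.integer(counts),
                        shell_step = shell_step)
  class(out) <- unique(c("sholl_profile", class(out)))
  out
}

#' Number of primary branches
#'
#' Primary branches are the processes emanating directly from the soma:
#' the root node's children.
#'
#' @param trace An `swc_neuron` tibble.
#' @return Integer count.
#' @export
primary_branch_count <- function(trace) {
  trace <- validate_swc(trace)
  root_id <- trace$id[trace$parent == -1]
  sum(trace$parent == root_id)
}

#' Total and per-tree process lengths
#'
#' Total length is the sum of Euclidean lengths of all parent-child segments
#' in the trace. One "tree" is the subtree rooted at each of the root's
#' children, including the root-to-child segment; the longest tree is the
#' maximal per-tree sum — the standard tracing-software reading of "length
#' of the longest tree".
#'
#' @param trace An `swc_neuron` tibble.
#' @return A list: `total_length` (µm), `longest_tree_length` (µm), and a
#'   tibble `trees` with per-primary-branch lengths.
#' @export
tree_lengths <- function(trace) {
  trace <- validate_swc(trace)
  root_id <- trace$id[trace$parent == -1]
  seg <- swc_segments(trace, "3d")
  if (nrow(seg) == 0) {
    return(list(total_length = 0, longest_tree_length = 0,
                trees = tibble::tibble(primary_id = integer(),
                                       length = numeric())))
  }
  # assign every node to the primary branch whose subtree contains it
  parent_of <- setNames(trace$parent, trace$id)
  primary_of <- function(id) {
    cur <- id
    repeat {
      p <- parent_of[[as.character(cur)]]
      if (p == root_id) return(cur)
      if (p == -1L) return(NA_integer_)  # the root itself
      cur <- p
    }
  }
  seg$primary <- vapply(seg$child_id, primary_of, integer(1))
  trees <- seg |>
    dplyr::group_by(primary_id = .data$primary) |>
    dplyr::summarise(length = sum(.data$length), .groups = "drop")
  list(
    total_length = sum(seg$length),
    longest_tree_length = max(trees$length),
    trees = trees
  )
}

#' Generate a random branching tree for oracle tests
#'
#' Grows a reproducible random SWC tree from the origin: `n_primaries`
#' processes leave the soma in random directions; each segment has random
#' length and, up to `max_order`, terminates or spawns two daughters with
#' probability `branch_prob`. Child directions perturb the parent direction,
#' so arbors grow outward. Ground-truth total length is recorded in the
#' `"total_length_true"` attribute.
#'
#' @param n_primaries Number of primary branches (>= 1).
#' @param branch_prob Probability a segment bifurcates, in `[0, 1]`.
#' @param mean_segment_um Mean segment length (exponential + floor), µm.
#' @param max_order Maximum branch order (>= 1).
#' @param seed Integer seed.
#' @return An `swc_neuron` tibble with attribute `total_length_true`.
#' @export
generate_tree <- function(n_primaries = 5, branch_prob = 0.3,
                          mean_segment_um = 15, max_order = 4, seed = 1) {
  if (n_primaries < 1 || branch_prob < 0 || branch_prob > 1 ||
      mean_segment_um <= 0 || max_order < 1) {
    abort("invalid tree parameters", class = "spinedyn_config_error")
  }
  withr::local_seed(as.integer(seed))
  nodes <- list(list(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                     radius = 1, parent = -1L))
  next_id <- 2L
  total <- 0

  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  grow <- function(parent_id, origin, dir, order) {
    len <- 2 + rexp(1, 1 / mean_segment_um)
    end <- origin + dir * len
    id <- next_id
    next_id <<- next_id + 1L
    nodes[[length(nodes) + 1]] <<- list(id = id, type = 3L, x = end[1],
                                        y = end[2], z = end[3],
                                        radius = 0.5, parent = parent_id)
    total <<- total + len
    if (order < max_order && runif(1) < branch_prob) {
      for (k in 1:2) {
        d <- dir + 0.6 * rand_dir()
        d <- d / sqrt(sum(d^2))
        grow(id, end, d, order + 1L)
      }
    }
  }
  for (i in seq_len(n_primaries)) {
    grow(1L, c(0, 0, 0), rand_dir(), 1L)
  }
  trace <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  trace <- validate_swc(trace)
  attr(trace, "total_length_true") <- total
  trace
}

#' Scalar morphometrics of a trace
#'
#' Convenience wrapper collecting the Fig-style per-cell measures: primary
#' branch count, longest-tree length and total process length.
#'
#' @param trace An `swc_neuron` tibble.
#' @return A one-row tibble.
#' @export
arbor_metrics <- function(trace) {
  tl <- tree_lengths(trace)
  tibble::tibble(
    n_primary_branches = primary_branch_count(trace),
    longest_tree_um = tl$longest_tree_length,
    total_length_um = tl$total_length
  )
}
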