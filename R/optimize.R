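# Path-set construction and the recursive DFS continuity optimizer.

new_path_set <- function(paths, graph) {
  nodes <- unlist(paths)
  n <- length(graph$x)
  ap_check(length(nodes) == n && !anyDuplicated(nodes) && all(sort(nodes) == seq_len(n)),
           "path_set: paths must cover every waypoint exactly once")
  structure(list(paths = paths, n_paths = length(paths), n_nodes = n),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  lens <- lengths(x$paths)
  cat(sprintf("Path set: %d paths over %d waypoints (lengths %s)\n",
              x$n_paths, x$n_nodes,
              if (length(lens)) paste(range(lens), collapse = "-") else "-"))
  invisible(x)
}

adjacency_list <- function(graph) {
  n <- length(graph$x)
  adj <- vector("list", n)
  if (nrow(graph$edges)) {
    e <- graph$edges
    both <- rbind(e, e[, 2:1, drop = FALSE])
    o <- order(both[, 1], both[, 2])
    both <- both[o, , drop = FALSE]
    adj <- split(both[, 2], factor(both[, 1], levels = seq_len(n)))
    adj <- lapply(adj, as.integer)
  } else {
    adj <- rep(list(integer(0)), n)
  }
  adj
}

#' Naive per-unit path decomposition
#'
#' The unoptimized baseline: every grid unit's serpentine pass is printed
#' as its own path (no cross-unit merging).  After trimming, a unit whose
#' pass was cut into pieces contributes one path per surviving piece.
#'
#' @param graph a `waypoint_graph`.
#' @return A `path_set`.
#' @export
naive_path_set <- function(graph) {
  n <- length(graph$x)
  if (n == 0L) return(new_path_set(list(), graph))
  # restrict to within-unit edges and walk each unit's chain fragments
  e <- graph$edges
  same <- graph$unit[e[, 1]] == graph$unit[e[, 2]]
  adj <- adjacency_list(list(x = graph$x, edges = e[same, , drop = FALSE]))
  visited <- logical(n)
  paths <- list()
  deg <- lengths(adj)
  # endpoints first so fragments are walked end-to-end
  for (s in order(deg >= 2, seq_len(n))) {
    if (visited[s]) next
    path <- s; visited[s] <- TRUE
    cur <- s
    repeat {
      nxt <- adj[[cur]][!visited[adj[[cur]]]]
      if (length(nxt) == 0L) break
      cur <- nxt[1]
      visited[cur] <- TRUE
      path <- c(path, cur)
    }
    paths[[length(paths) + 1L]] <- path
  }
  new_path_set(paths, graph)
}

# longest simple path from `start` in the unvisited subgraph, by bounded
# exhaustive depth-first search (explicit stack, deterministic neighbor
# order).  `budget` caps the number of node expansions; the best path
# found so far is returned if it is exhausted.
longest_from <- function(start, adj, blocked, budget = 20000L) {
  n <- length(blocked)
  path <- integer(n); iters <- vector("list", n)
  onpath <- logical(n)
  depth <- 1L
  path[1] <- start; onpath[start] <- TRUE
  iters[[1]] <- adj[[start]]
  best <- integer(0); bestlen <- 0L
  expansions <- 0L
  while (depth > 0L) {
    nbrs <- iters[[depth]]
    adv <- FALSE
    while (length(nbrs)) {
      v <- nbrs[1]
      nbrs <- nbrs[-1]
      if (!onpath[v] && !blocked[v]) {
        iters[[depth]] <- nbrs
        depth <- depth + 1L
        path[depth] <- v; onpath[v] <- TRUE
        iters[[depth]] <- adj[[v]]
        expansions <- expansions + 1L
        adv <- TRUE
        break
      }
    }
    if (!adv) {
      if (depth > bestlen) { bestlen <- depth; best <- path[seq_len(depth)] }
      onpath[path[depth]] <- FALSE
      depth <- depth - 1L
      if (expansions > budget) {
        # unwind: best found so far wins
        while (depth > 0L) { onpath[path[depth]] <- FALSE; depth <- depth - 1L }
        break
      }
      next
    }
    if (expansions > budget) {
      if (depth > bestlen) { bestlen <- depth; best <- path[seq_len(depth)] }
      while (depth > 0L) { onpath[path[depth]] <- FALSE; depth <- depth - 1L }
      break
    }
  }
  best
}

# one full decomposition pass: random seeds, forward + reverse extension
decompose_once <- function(adj, n, budget) {
  visited <- logical(n)
  order_perm <- sample.int(n)
  paths <- list()
  for (s in order_perm) {
    if (visited[s]) next
    fwd <- longest_from(s, adj, visited, budget)
    visited[fwd] <- TRUE
    visited[s] <- FALSE  # allow the reverse pass to re-anchor at the seed
    blocked2 <- visited
    blocked2[fwd] <- TRUE
    blocked2[s] <- FALSE
    bwd <- longest_from(s, adj, blocked2, budget)
    visited[s] <- TRUE
    visited[bwd] <- TRUE
    full <- c(rev(bwd[-1]), fwd)
    paths[[length(paths) + 1L]] <- full
  }
  paths
}

count_reversals <- function(paths, graph) {
  total <- 0L
  for (p in paths) {
    if (length(p) < 3L) next
    dx <- diff(graph$x[p]); dy <- diff(graph$y[p])
    dots <- dx[-length(dx)] * dx[-1] + dy[-length(dy)] * dy[-1]
    total <- total + sum(dots < 0)
  }
  total
}

#' Minimize the number of distinct extrusion paths
#'
#' Decomposes the waypoint graph into node-disjoint continuous paths
#' using the randomized recursive depth-first-search heuristic: pick a
#' random untraversed seed waypoint, extend forward to the longest
#' reachable continuation (branches explored depth-first, longest branch
#' kept), extend similarly in reverse from the seed, retire the traversed
#' waypoints, and repeat until the seed pool is empty.  The whole pass is
#' restarted `restarts` times with fresh random seeds and the
#' decomposition with the fewest paths is kept (ties: fewest direction
#' reversals, then first found).  The naive per-unit decomposition is
#' always included as a candidate, so the result never has more paths
#' than no optimization.
#'
#' @param graph a `waypoint_graph`.
#' @param restarts number of random restarts (>= 1, default 100).
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#'   One random seed-order permutation is drawn per restart, in restart
#'   order.
#' @param budget per-seed cap on DFS node expansions (default 20000).
#' @return A `path_set`.
#' @export
optimize_paths <- function(graph, restarts = 100L, seed = 1L, budget = 20000L) {
  ap_check(inherits(graph, "waypoint_graph"), "optimize_paths: `graph` must be a waypoint_graph")
  ap_check(restarts >= 1L, "optimize_paths: `restarts` must be >= 1")
  n <- length(graph$x)
  if (n == 0L) return(new_path_set(list(), graph))
  adj <- adjacency_list(graph)
  ap_with_seed(seed, {
    # the naive per-unit decomposition is always a candidate, so the
    # optimizer can never do worse than no optimization
    best <- naive_path_set(graph)$paths
    best_rev <- NA_integer_
    for (r in seq_len(restarts)) {
      paths <- decompose_once(adj, n, budget)
      if (length(paths) < length(best)) {
        best <- paths; best_rev <- NA_integer_
      } else if (length(paths) == length(best)) {
        if (is.na(best_rev)) best_rev <- count_reversals(best, graph)
        rv <- count_reversals(paths, graph)
        if (rv < best_rev) { best <- paths; best_rev <- rv }
      }
    }
    new_path_set(best, graph)
  })
}

#' Continuity metrics of a path decomposition
#'
#' @param paths a `path_set`.
#' @param graph the `waypoint_graph` the paths decompose.
#' @param baseline_unit_waypoints the single-unit path length (waypoints)
#'   of the naive traversal; coverage counts waypoints in paths strictly
#'   longer than this.
#' @return List of class `path_metrics`: `n_paths`, `waypoints_per_path`,
#'   `naive_n_paths`, `reduction_pct`, `coverage_pct`.
#' @export
path_metrics <- function(paths, graph, baseline_unit_waypoints = 10L) {
  ap_check(inherits(paths, "path_set"), "path_metrics: `paths` must be a path_set")
  ap_check(inherits(graph, "waypoint_graph"), "path_metrics: `graph` must be a waypoint_graph")
  ap_check(paths$n_nodes == length(graph$x), "path_metrics: paths do not match graph")
  naive <- naive_path_set(graph)
  lens <- lengths(paths$paths)
  structure(list(
    n_paths = paths$n_paths,
    waypoints_per_path = lens,
    naive_n_paths = naive$n_paths,
    reduction_pct = 100 * (1 - paths$n_paths / naive$n_paths),
    coverage_pct = 100 * sum(lens[lens > baseline_unit_waypoints]) /
      max(1L, paths$n_nodes)),
    class = "path_metrics")
}

#' @export
print.path_metrics <- function(x, ...) {
  cat(sprintf("Paths: %d (naive %d) | reduction %.1f%% | coverage in merged paths %.1f%%\n",
              x$n_paths, x$naive_n_paths, x$reduction_pct, x$coverage_pct))
  invisible(x)
}

#' Export a path set as CSV
#'
#' Writes columns `path_id`, `order`, `x`, `y`.
#'
#' @param paths a `path_set`.
#' @param graph its `waypoint_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_path_set <- function(paths, graph, path) {
  rows <- do.call(rbind, lapply(seq_along(paths$paths), function(i) {
    p <- paths$paths[[i]]
    data.frame(path_id = i, order = seq_along(p),
               x = graph$x[p], y = graph$y[p])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
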