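# Synthetic instance generators and search oracles: random genome pairs
# derived by random DCJs, random Eulerian multigraphs, the reduction turning
# any connected Eulerian multigraph into an MLS instance whose junction graph
# is that graph, an exhaustive minimum-cost search over colored DCJ states,
# and a planted-cluster Hi-C simulator.

# all structural DCJ moves available on genome g, as a deterministic list of
# list(consumed = keys, produced = list of adjacencies)
enumerate_structural_moves <- function(g) {
  keys <- names(g$adjacencies)
  internals <- keys[lengths(g$adjacencies) == 2L]
  externals <- keys[lengths(g$adjacencies) == 1L]
  moves <- list()
  add <- function(consumed, produced) {
    moves[[length(moves) + 1L]] <<- list(consumed = consumed, produced = produced)
  }
  ni <- length(internals)
  if (ni >= 2L) {
    for (i in seq_len(ni - 1L)) {
      for (j in seq(i + 1L, ni)) {
        p <- g$adjacencies[[internals[i]]]
        q <- g$adjacencies[[internals[j]]]
        add(c(internals[i], internals[j]),
            list(c(p[1], q[1]), c(p[2], q[2])))
        add(c(internals[i], internals[j]),
            list(c(p[1], q[2]), c(p[2], q[1])))
      }
    }
  }
  for (ik in internals) {
    p <- g$adjacencies[[ik]]
    for (ek in externals) {
      c_ <- g$adjacencies[[ek]]
      add(c(ik, ek), list(c(p[1], c_), p[2]))
      add(c(ik, ek), list(c(p[2], c_), p[1]))
    }
    add(ik, list(p[1], p[2])) # split
  }
  ne <- length(externals)
  if (ne >= 2L) {
    for (i in seq_len(ne - 1L)) {
      for (j in seq(i + 1L, ne)) {
        add(c(externals[i], externals[j]),
            list(c(g$adjacencies[[externals[i]]], g$adjacencies[[externals[j]]])))
      }
    }
  }
  moves
}

#' Random genome pair derived by random DCJ moves
#'
#' Builds an identity genome *A* with `n_blocks` blocks spread over
#' `n_linear_chromosomes` linear chromosomes (as evenly as possible), then
#' derives *B* by applying `n_moves` structural DCJ moves drawn uniformly
#' from all legal moves at each step.
#'
#' @param n_blocks number of syntenic blocks (>= 1).
#' @param n_linear_chromosomes number of linear chromosomes of *A*
#'   (1 .. `n_blocks`).
#' @param n_moves number of random DCJs applied to reach *B*.
#' @param seed integer seed.
#' @return an object of class `"instance_bundle"`: `A`, `B` ([genome()]s over
#'   the same universe), `block` (the block genome of *A*), `map` (extremity
#'   map) and `provenance`. No coloring is attached; use [random_coloring()],
#'   [linear_coloring()] or [kmedoids_coloring()].
#' @export
random_genome_pair <- function(n_blocks, n_linear_chromosomes = 1L,
                               n_moves = 0L, seed = NULL) {
  if (n_blocks < 1L) abort("need at least one block")
  if (n_linear_chromosomes < 1L || n_linear_chromosomes > n_blocks) {
    abort("need 1 <= n_linear_chromosomes <= n_blocks")
  }
  if (n_moves < 0L) abort("n_moves must be nonnegative")
  sizes <- rep(n_blocks %/% n_linear_chromosomes, n_linear_chromosomes)
  extra <- n_blocks %% n_linear_chromosomes
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stopifnot(sum(sizes) == n_blocks)
  next_b <- 1L
  chroms <- lapply(sizes, function(s) {
    b <- as.character(seq(next_b, next_b + s - 1L))
    next_b <<- next_b + s
    list(blocks = b, signs = rep(1L, s), circular = FALSE)
  })
  bg <- structure(chroms, class = "block_genome")
  ba <- block_to_adjacency(bg)
  A <- ba$genome
  B <- A
  dummy <- coloring(A, rep("c", length(A$adjacencies)))
  with_seed(seed, {
    for (step in seq_len(n_moves)) {
      cand <- enumerate_structural_moves(B)
      pick <- cand[[sample.int(length(cand), 1L)]]
      mv <- dcj_move(B$adjacencies[pick$consumed], pick$produced,
                     rep("c", length(pick$consumed)),
                     rep("c", length(pick$produced)))
      B <- apply_move(B, dummy, mv)$genome
      dummy <- coloring(B, rep("c", length(B$adjacencies)))
    }
  })
  structure(
    list(A = A, B = B, block = bg, map = ba$map,
         provenance = list(generator = "random_genome_pair",
                           n_blocks = n_blocks,
                           n_linear_chromosomes = n_linear_chromosomes,
                           n_moves = n_moves, seed = seed)),
    class = "instance_bundle"
  )
}

#' @export
print.instance_bundle <- function(x, ...) {
  cat("instance bundle (", x$provenance$generator %||% "unknown", "):\n",
      sep = "")
  cat("  A:", format(x$A), "\n  B:", format(x$B), "\n")
  if (!is.null(x$coloring)) {
    cat("  palette:", paste(attr(x$coloring, "palette"), collapse = ", "), "\n")
  }
  invisible(x)
}

# deterministic Eulerian circuit (Hierholzer, smallest-neighbor tie-break);
# returns the closed vertex walk u1, ..., ue (ue joins back to u1)
euler_tour <- function(g) {
  e <- g$edges
  deg <- degrees(g)
  if (!is_eulerian(g)) abort("graph is not Eulerian")
  if (any(deg == 0L)) abort("graph has isolated vertices; not connected")
  if (!mg_is_connected(g)) abort("graph is not connected")
  used <- logical(nrow(e))
  start <- sort(g$vertices)[1]
  stack_v <- start
  walk <- character(0)
  while (length(stack_v)) {
    v <- stack_v[length(stack_v)]
    cand <- which(!used & (e$u == v | e$v == v))
    if (length(cand)) {
      nb <- ifelse(e$u[cand] == v, e$v[cand], e$u[cand])
      pick <- cand[order(nb, e$id[cand])][1]
      used[pick] <- TRUE
      stack_v <- c(stack_v, if (e$u[pick] == v) e$v[pick] else e$u[pick])
    } else {
      walk <- c(walk, v)
      stack_v <- stack_v[-length(stack_v)]
    }
  }
  walk <- rev(walk)
  if (length(walk) != nrow(e) + 1L || walk[1] != walk[length(walk)]) {
    abort("internal error: Eulerian tour construction failed")
  }
  walk[-length(walk)]
}

#' MLS instance from a connected Eulerian multigraph
#'
#' Realizes a connected Eulerian multigraph as the junction graph of a
#' circular-genome MLS instance: along an Eulerian tour `u1, ..., un` it
#' emits `A = {{1,2}, ..., {2n-1,2n}}`, `B = {{2,3}, ..., {2n,1}}` and
#' colors `col({2i-1, 2i}) = u_i`. The junction graph of the instance is
#' checked to equal the input graph (as an endpoint multiset). Since
#' edge-disjoint cycle packing is hard on Eulerian graphs, this doubles as a
#' generator of hard, verified test instances.
#'
#' @param g a connected Eulerian [multigraph()] with at least one edge.
#' @return an `"instance_bundle"` with `A`, `B`, `coloring`, the source
#'   `graph` and the `tour` used.
#' @examples
#' tri <- multigraph(c("a", "b", "c"),
#'                   data.frame(u = c("a", "b", "c"), v = c("b", "c", "a")))
#' inst <- instance_from_eulerian_graph(tri)
#' mls_cost(inst$A, inst$B, inst$coloring)$cost # e - c = 3 - 1
#' @export
instance_from_eulerian_graph <- function(g) {
  if (!nrow(g$edges)) abort("graph has no edges")
  tour <- euler_tour(g)
  n <- length(tour)
  A <- genome(lapply(seq_len(n), function(i) c(2L * i - 1L, 2L * i)))
  B <- genome(lapply(seq_len(n), function(i)
    c(2L * i, if (i < n) 2L * i + 1L else 1L)))
  col <- coloring(A, stats::setNames(
    tour, vapply(seq_len(n), function(i) adj_key(c(2L * i - 1L, 2L * i)),
                 character(1))
  ))
  J <- build_junction_graph(A, B, col)
  if (!identical(multigraph_key(J), multigraph_key(g))) {
    abort("internal error: junction graph of the reduction differs from the input")
  }
  structure(
    list(A = A, B = B, coloring = col, graph = g, tour = tour,
         provenance = list(generator = "instance_from_eulerian_graph")),
    class = "instance_bundle"
  )
}

#' Random Eulerian multigraph
#'
#' Union of random closed walks: walk lengths are drawn until the requested
#' edge count is reached exactly, so every vertex degree is even by
#' construction.
#'
#' @param n_vertices,n_edges sizes (both >= 1).
#' @param seed integer seed.
#' @param connected require a connected result with no isolated vertex
#'   (rejection-sampled; errors after 1000 attempts).
#' @return a [multigraph()] with vertices `"v1" .. "vN"`.
#' @export
random_eulerian_multigraph <- function(n_vertices, n_edges, seed = NULL,
                                       connected = FALSE) {
  if (n_vertices < 1L || n_edges < 1L) abort("need positive sizes")
  if (connected && n_vertices >= 2L && n_edges < n_vertices) {
    # a union of closed walks covering v >= 2 vertices needs >= v edges
    abort("too few edges for a connected Eulerian graph on ", n_vertices,
          " vertices")
  }
  verts <- paste0("v", seq_len(n_vertices))
  with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      u <- character(0)
      v <- character(0)
      remaining <- n_edges
      while (remaining > 0L) {
        len <- sample.int(remaining, 1L)
        vs <- sample(verts, len, replace = TRUE)
        u <- c(u, vs)
        v <- c(v, c(vs[-1], vs[1]))
        remaining <- remaining - len
      }
      g <- multigraph(verts, data.frame(u = u, v = v, stringsAsFactors = FALSE))
      if (!connected) return(g)
      if (all(degrees(g) > 0L) && mg_is_connected(g)) return(g)
    }
    abort("could not draw a connected Eulerian multigraph; relax the sizes")
  })
}

#' Exhaustive minimum-cost scenario search (test oracle)
#'
#' Breadth-first search over colored-DCJ states ordered by non-local count:
#' within a cost layer the zero-cost closure is explored fully before
#' promoting cost-one successors. States are merged when they share the same
#' junction graph and the same colored adjacency-graph component structure;
#' the search stops at the first state whose junction graph is terminal,
#' from which the target genome is reachable by zero-cost moves alone.
#' Intended for tiny instances only; independent of the cycle-packing
#' solvers and of the constructive scenario builder.
#'
#' @param A,B [genome()]s over the same universe.
#' @param col a [coloring()] of `A`.
#' @param cost_cap stop (with an error) when the cost exceeds this.
#' @param max_states abort when more distinct states have been visited.
#' @return the minimum number of non-local moves of a scenario transforming
#'   `A` into `B`.
#' @export
exhaustive_min_cost_search <- function(A, B, col, cost_cap = Inf,
                                       max_states = 200000L) {
  if (!setequal(A$universe, B$universe)) {
    abort("genomes are over different extremity universes")
  }
  palette <- sort(unique(unname(col)))
  K <- length(palette)
  maxext <- max(A$universe)
  b_adj <- unname(B$adjacencies)
  nB <- length(b_adj)
  b_of <- integer(maxext)
  for (i in seq_len(nB)) for (e in b_adj[[i]]) b_of[e] <- i
  b_internal <- b_adj[lengths(b_adj) == 2L]
  b_lens <- lengths(b_adj)

  new_state <- function(adjlist, cols) {
    owner <- integer(maxext)
    for (i in seq_along(adjlist)) for (e in adjlist[[i]]) owner[e] <- i
    list(adj = adjlist, col = cols, owner = owner)
  }

  # goal: a terminal junction graph -- from there B is reachable at zero
  # cost (create every missing internal adjacency of B with same-colored
  # moves, split the surplus), so the first terminal layer gives the minimum
  is_terminal_state <- function(s) {
    for (p in b_internal) {
      if (s$col[s$owner[p[1]]] != s$col[s$owner[p[2]]]) return(FALSE)
    }
    TRUE
  }

  # merge key: junction-graph edge multiset + colored component structure of
  # the adjacency graph against B (union-find, integer-coded colors)
  state_key <- function(s) {
    nj <- length(b_internal)
    jp <- integer(nj)
    if (nj) {
      for (i in seq_len(nj)) {
        p <- b_internal[[i]]
        c1 <- s$col[s$owner[p[1]]]
        c2 <- s$col[s$owner[p[2]]]
        jp[i] <- if (c1 <= c2) c1 * 64L + c2 else c2 * 64L + c1
      }
      jp <- sort.int(jp, method = "radix")
    }
    nA <- length(s$adj)
    parent <- seq_len(nA + nB)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (e in seq_len(maxext)) {
      if (s$owner[e] > 0L) {
        r1 <- find(s$owner[e])
        r2 <- find(nA + b_of[e])
        if (r1 != r2) parent[r2] <- r1
      }
    }
    lens <- lengths(s$adj)
    roots_state <- vapply(seq_len(nA), find, integer(1))
    roots_b <- vapply(nA + seq_len(nB), find, integer(1))
    comp_sig <- character(0)
    for (r in unique(roots_state)) {
      mem_s <- roots_state == r
      is_path <- any(lens[mem_s] == 1L) || any(b_lens[roots_b == r] == 1L)
      comp_sig <- c(comp_sig, paste(
        (if (is_path) 1L else 0L) * 100000L + sum(lens[mem_s]) * 1000L,
        paste(tabulate(s$col[mem_s], K), collapse = ""), sep = "_"))
    }
    paste(paste(jp, collapse = ","),
          paste(sort.int(comp_sig, method = "radix"), collapse = ";"),
          sep = "#")
  }

  successors <- function(s) {
    out <- list()
    push <- function(consumed_idx, produced, pcols, cost) {
      st <- new_state(c(s$adj[-consumed_idx], produced),
                      c(s$col[-consumed_idx], pcols))
      st$cost <- cost
      out[[length(out) + 1L]] <<- st
    }
    lens <- lengths(s$adj)
    I <- which(lens == 2L)
    E <- which(lens == 1L)
    if (length(I) >= 2L) {
      for (ii in seq_len(length(I) - 1L)) {
        for (jj in seq(ii + 1L, length(I))) {
          i <- I[ii]; j <- I[jj]
          p <- s$adj[[i]]; q <- s$adj[[j]]
          x <- s$col[i]; y <- s$col[j]
          cost <- if (x == y) 0L else 1L
          for (prod in list(list(c(p[1], q[1]), c(p[2], q[2])),
                            list(c(p[1], q[2]), c(p[2], q[1])))) {
            push(c(i, j), prod, c(x, y), cost)
            if (x != y) push(c(i, j), prod, c(y, x), cost)
          }
        }
      }
    }
    for (i in I) {
      p <- s$adj[[i]]; x <- s$col[i]
      for (j in E) {
        e <- s$adj[[j]]; y <- s$col[j]
        cost <- if (x == y) 0L else 1L
        for (prod in list(list(c(p[1], e), p[2]),
                          list(c(p[2], e), p[1]))) {
          push(c(i, j), prod, c(x, y), cost)
          if (x != y) push(c(i, j), prod, c(y, x), cost)
        }
      }
      for (z in seq_len(K)) {
        push(i, list(p[1], p[2]), c(x, z), if (z == x) 0L else 1L)
        if (z != x) push(i, list(p[1], p[2]), c(z, x), 1L)
      }
    }
    if (length(E) >= 2L) {
      for (ii in seq_len(length(E) - 1L)) {
        for (jj in seq(ii + 1L, length(E))) {
          i <- E[ii]; j <- E[jj]
          x <- s$col[i]; y <- s$col[j]
          cost <- if (x == y) 0L else 1L
          prod <- list(c(s$adj[[i]], s$adj[[j]]))
          push(c(i, j), prod, x, cost)
          if (x != y) push(c(i, j), prod, y, cost)
        }
      }
    }
    out
  }

  cols0 <- match(unname(col[names(A$adjacencies)]), palette)
  s0 <- new_state(unname(A$adjacencies), cols0)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_key(s0), TRUE, envir = visited)
  n_states <- 1L
  layer <- list(s0)
  cost <- 0L
  repeat {
    queue <- layer
    nxt <- list()
    nxt_keys <- new.env(hash = TRUE, parent = emptyenv())
    qi <- 1L
    while (qi <= length(queue)) {
      s <- queue[[qi]]
      qi <- qi + 1L
      if (is_terminal_state(s)) return(cost)
      for (s2 in successors(s)) {
        k2 <- state_key(s2)
        if (s2$cost == 0L) {
          if (!exists(k2, envir = visited, inherits = FALSE)) {
            assign(k2, TRUE, envir = visited)
            n_states <- n_states + 1L
            if (n_states > max_states) abort("state cap exceeded at ", n_states)
            queue[[length(queue) + 1L]] <- s2
          }
        } else if (!exists(k2, envir = visited, inherits = FALSE) &&
                   !exists(k2, envir = nxt_keys, inherits = FALSE)) {
          assign(k2, TRUE, envir = nxt_keys)
          s2$key <- k2
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    cost <- cost + 1L
    if (cost > cost_cap) abort("cost cap exceeded")
    layer <- list()
    for (s in nxt) {
      if (!exists(s$key, envir = visited, inherits = FALSE)) {
        assign(s$key, TRUE, envir = visited)
        n_states <- n_states + 1L
        if (n_states > max_states) abort("state cap exceeded at ", n_states)
        layer[[length(layer) + 1L]] <- s
      }
    }
    if (!length(layer)) abort("search exhausted without reaching the target")
  }
}

#' Synthetic Hi-C dataset with planted 3D clusters
#'
#' Raw contacts follow a steep geometric distance decay within chromosomes
#' (so the mean contact is nonincreasing in distance regardless of the
#' planting), a flat low background between chromosomes, and a multiplicative
#' boost for bin pairs in the same planted cluster. Optional log-normal
#' noise.
#'
#' @param n_chroms,bins_per_chrom layout sizes.
#' @param planted_clusters number of planted clusters (bins are assigned
#'   round-robin, then shuffled).
#' @param noise standard deviation of multiplicative log-normal noise
#'   (0 = none).
#' @param seed integer seed.
#' @param boost within-cluster contact multiplier is `1 + boost`.
#' @return a list with `hic` (a [hic_dataset()]) and `truth` (integer cluster
#'   label per bin).
#' @export
synthetic_hic <- function(n_chroms = 2L, bins_per_chrom = 6L,
                          planted_clusters = 2L, noise = 0, seed = NULL,
                          boost = 5) {
  n <- n_chroms * bins_per_chrom
  if (planted_clusters < 1L || planted_clusters > n) {
    abort("planted_clusters must be between 1 and the bin count")
  }
  width <- 10000L
  bins <- data.frame(
    chrom = rep(paste0("chr", seq_len(n_chroms)), each = bins_per_chrom),
    start = rep((seq_len(bins_per_chrom) - 1L) * width, n_chroms),
    end = rep(seq_len(bins_per_chrom) * width, n_chroms),
    bin = seq_len(n),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    truth <- sample(rep_len(seq_len(planted_clusters), n))
    same_chrom <- outer(bins$chrom, bins$chrom, "==")
    off <- bin_offsets(bins)
    dmat <- abs(outer(off, off, "-"))
    same_cluster <- outer(truth, truth, "==")
    # power-law decay within chromosomes, flat background between them; the
    # planted boost is mean-corrected per distance stratum so the average
    # contact at each distance is exactly the decay curve (nonincreasing)
    H <- matrix(0, n, n)
    lift <- 1 + boost * same_cluster
    for (d in sort(unique(dmat[same_chrom]))) {
      sel <- same_chrom & dmat == d
      H[sel] <- (100 / (1 + d)) * lift[sel] / mean(lift[sel])
    }
    if (any(!same_chrom)) {
      H[!same_chrom] <- 2 * lift[!same_chrom] / mean(lift[!same_chrom])
    }
    if (noise > 0) {
      eps <- matrix(stats::rnorm(n * n, sd = noise), n, n)
      eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
      H <- H * exp(eps)
    }
    list(hic = hic_dataset(bins, H), truth = truth)
  })
}

#' Enumerate small Eulerian multigraphs
#'
#' All multigraphs with at most `max_vertices` vertices and 1 to `max_edges`
#' edges, every vertex of positive even degree, optionally connected,
#' deduplicated up to vertex relabeling.
#'
#' @param max_vertices,max_edges enumeration bounds (keep small; the count
#'   grows quickly).
#' @param connected keep only connected graphs (default `TRUE`).
#' @return a list of [multigraph()]s.
#' @export
enumerate_eulerian_multigraphs <- function(max_vertices, max_edges,
                                           connected = TRUE) {
  out <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(max_vertices)) {
    verts <- paste0("v", seq_len(k))
    types <- list()
    for (i in seq_len(k)) {
      for (j in i:k) types[[length(types) + 1L]] <- c(verts[i], verts[j])
    }
    perms <- all_permutations(k)
    # multisets of edge types: counts per type summing to 1..max_edges
    rec <- function(ti, left, counts) {
      if (ti > length(types)) {
        if (left == max_edges) return() # no edges at all
        m <- max_edges - left
        u <- character(0)
        v <- character(0)
        for (t in seq_along(counts)) {
          if (counts[t]) {
            u <- c(u, rep(types[[t]][1], counts[t]))
            v <- c(v, rep(types[[t]][2], counts[t]))
          }
        }
        g <- multigraph(verts, data.frame(u = u, v = v,
                                          stringsAsFactors = FALSE))
        if (!is_eulerian(g) || any(degrees(g) == 0L)) return()
        if (connected && !mg_is_connected(g)) return()
        key <- canonical_multigraph_key(g, verts, perms)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <<- g
        }
        return()
      }
      for (c_ in 0:left) {
        counts[ti] <- c_
        rec(ti + 1L, left - c_, counts)
      }
    }
    rec(1L, max_edges, integer(length(types)))
  }
  out
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

canonical_multigraph_key <- function(g, verts, perms) {
  best <- NULL
  for (p in perms) {
    relab <- stats::setNames(verts[p], verts)
    e2 <- g$edges
    e2$u <- unname(relab[e2$u])
    e2$v <- unname(relab[e2$v])
    key <- multigraph_key(list(edges = e2))
    if (is.null(best) || key < best) best <- key
  }
  best
}

#' Minimum 2-break sorting distance by breadth-first search (test oracle)
#'
#' BFS over multigraph states (all 2-breaks on all edge pairs) until a
#' terminal graph -- every edge a loop -- is reached. Independent of
#' [two_break_sort()] and of cycle packings; intended for small graphs.
#'
#' @param g an Eulerian [multigraph()].
#' @param max_states abort beyond this many visited states.
#' @return the minimum number of 2-breaks to a terminal graph.
#' @export
min_two_break_sort_length <- function(g, max_states = 200000L) {
  if (is_terminal(g)) return(0L)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(multigraph_key(g), TRUE, envir = visited)
  frontier <- list(g)
  depth <- 0L
  n_states <- 1L
  repeat {
    depth <- depth + 1L
    nxt <- list()
    for (s in frontier) {
      m <- nrow(s$edges)
      for (i in seq_len(m - 1L)) {
        for (j in seq(i + 1L, m)) {
          a <- s$edges$u[i]; b <- s$edges$v[i]
          c_ <- s$edges$u[j]; d <- s$edges$v[j]
          for (prod in list(list(c(a, c_), c(b, d)), list(c(a, d), c(b, c_)))) {
            s2 <- s
            s2$edges$u[c(i, j)] <- c(prod[[1]][1], prod[[2]][1])
            s2$edges$v[c(i, j)] <- c(prod[[1]][2], prod[[2]][2])
            key <- multigraph_key(s2)
            if (!exists(key, envir = visited, inherits = FALSE)) {
              if (is_terminal(s2)) return(depth)
              assign(key, TRUE, envir = visited)
              n_states <- n_states + 1L
              if (n_states > max_states) abort("state cap exceeded")
              nxt[[length(nxt) + 1L]] <- s2
            }
          }
        }
      }
    }
    if (!length(nxt)) abort("no terminal graph reachable (is the graph Eulerian?)")
    frontier <- nxt
  }
}
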