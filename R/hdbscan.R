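#' Hierarchical density-based clustering with noise (HDBSCAN)
#'
#' Density-based clustering of a point set with an explicit noise label.
#' Implements the standard HDBSCAN pipeline: core distances from the
#' `min_samples`-nearest neighbourhood, a minimum spanning tree of the mutual
#' reachability graph, the single-linkage hierarchy condensed at
#' `min_cluster_size`, and excess-of-mass cluster selection. Points not in
#' any persistent density cluster receive label -1.
#'
#' The mutual reachability MST is built over a k-nearest-neighbour graph
#' (`k_graph` neighbours per point) rather than the complete graph; this is
#' the usual large-n approximation and is exact whenever each point's true
#' MST neighbours are within its k nearest, which holds for all but
#' adversarial geometries at the default `k_graph`.
#'
#' @param X Numeric matrix of points (rows) -- here, 2-D embedding
#'   coordinates.
#' @param min_cluster_size Smallest number of points a cluster may contain
#'   (default 200).
#' @param min_samples Neighbourhood size for the core-distance estimate
#'   (default 30); the point itself counts as its own first neighbour.
#' @param k_graph Neighbours per point in the graph used for the MST
#'   (default `max(2 * min_samples, 20)`).
#' @return A list with `labels` (integer per row of `X`: 0-based cluster ids
#'   in order of discovery, -1 = noise), `n_clusters`, and `cluster_sizes`.
#' @export
hdbscan_cluster <- function(X, min_cluster_size = 200, min_samples = 30,
                            k_graph = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < max(min_cluster_size, 2))
    return(list(labels = rep(-1L, n), n_clusters = 0L,
                cluster_sizes = integer(0)))
  if (is.null(k_graph)) k_graph <- max(2 * min_samples, 20)
  k <- min(n - 1, max(k_graph, min_samples))
  knn <- FNN::get.knn(X, k = k)
  # core distance: distance to the min_samples-th neighbour counting the
  # point itself, i.e. the (min_samples - 1)-th excluding self
  cs <- max(1L, min(min_samples - 1L, k))
  core <- knn$nn.dist[, cs]

  src <- rep(seq_len(n), k)
  dst <- as.vector(knn$nn.index)
  w <- pmax(as.vector(knn$nn.dist), core[src], core[dst])
  g <- igraph::graph_from_edgelist(cbind(src, dst), directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mst, names = FALSE)
  ew <- igraph::E(mst)$weight
  # bridge a disconnected forest so one hierarchy spans all points; the
  # bridges are heavier than every real edge, so they only add top-level
  # splits that condensation treats like any sparse region
  comp <- igraph::components(mst)
  if (comp$no > 1) {
    reps <- vapply(seq_len(comp$no), function(cid)
      which(comp$membership == cid)[1], integer(1))
    bridge_w <- 2 * max(ew, core, 1e-12)
    el <- rbind(el, cbind(reps[-length(reps)], reps[-1]))
    ew <- c(ew, rep(bridge_w, comp$no - 1))
  }
  hb <- hdbscan_labels_from_mst(el, ew, n, min_cluster_size)
  hb
}

# Single-linkage tree from MST edges, condensed tree, EOM selection, labels.
hdbscan_labels_from_mst <- function(edges, weights, n, min_cluster_size) {
  ord <- order(weights)
  edges <- edges[ord, , drop = FALSE]
  weights <- weights[ord]
  m <- nrow(edges)                     # = n - 1

  # union-find with path halving
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_of <- seq_len(n)                # current SL node sitting at each root
  sl_left <- sl_right <- integer(m)    # children of internal node n + j
  sl_dist <- numeric(m)
  sl_size <- integer(n + m)
  sl_size[seq_len(n)] <- 1L
  for (j in seq_len(m)) {
    ru <- find(edges[j, 1]); rv <- find(edges[j, 2])
    sl_left[j] <- node_of[ru]
    sl_right[j] <- node_of[rv]
    sl_dist[j] <- weights[j]
    sl_size[n + j] <- sl_size[node_of[ru]] + sl_size[node_of[rv]]
    parent[ru] <- rv
    node_of[rv] <- n + j
  }
  root <- n + m

  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack) > 0) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd <= n) out <- c(out, nd)
      else stack <- c(stack, sl_left[nd - n], sl_right[nd - n])
    }
    out
  }

  # ---- condensed tree ----------------------------------------------------
  max_cl <- 2L * as.integer(ceiling(n / min_cluster_size)) + 2L
  cl_parent <- integer(max_cl); cl_birth <- numeric(max_cl)
  cl_stab <- numeric(max_cl); cl_children <- vector("list", max_cl)
  n_cl <- 1L
  cl_parent[1] <- 0L; cl_birth[1] <- 0
  point_cluster <- rep(1L, n)
  point_lambda <- rep(NA_real_, n)

  # stack of (sl internal node, condensed cluster id)
  st_node <- root; st_cl <- 1L
  while (length(st_node) > 0) {
    nd <- st_node[length(st_node)]; cl <- st_cl[length(st_cl)]
    st_node <- st_node[-length(st_node)]; st_cl <- st_cl[-length(st_cl)]
    if (nd <= n) {          # singleton reaching lambda = infinity; close out
      point_cluster[nd] <- cl
      point_lambda[nd] <- NA_real_   # resolved below from parent's edges
      next
    }
    j <- nd - n
    d <- sl_dist[j]
    lam <- if (d > 0) 1 / d else .Machine$double.xmax^0.25
    L <- sl_left[j]; R <- sl_right[j]
    sL <- sl_size[L]; sR <- sl_size[R]
    bigL <- sL >= min_cluster_size
    bigR <- sR >= min_cluster_size
    if (bigL && bigR) {
      for (child in c(L, R)) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cl
        cl_birth[n_cl] <- lam
        cl_children[[cl]] <- c(cl_children[[cl]], n_cl)
        cl_stab[cl] <- cl_stab[cl] + sl_size[child] * (lam - cl_birth[cl])
        st_node <- c(st_node, child); st_cl <- c(st_cl, n_cl)
      }
    } else {
      for (child in c(L, R)) {
        big <- if (child == L) bigL else bigR
        if (big) {
          st_node <- c(st_node, child); st_cl <- c(st_cl, cl)
        } else {
          pts <- leaves_under(child)
          point_cluster[pts] <- cl
          point_lambda[pts] <- lam
          cl_stab[cl] <- cl_stab[cl] + length(pts) * (lam - cl_birth[cl])
        }
      }
    }
  }
  # lone continuing points that never fell out (numeric safety)
  open <- is.na(point_lambda)
  if (any(open)) point_lambda[open] <- cl_birth[point_cluster[open]]

  # ---- excess-of-mass selection (root never selectable) ------------------
  selected <- rep(FALSE, n_cl)
  for (cl in n_cl:1) {
    kids <- cl_children[[cl]]
    if (cl == 1L) break
    if (length(kids) == 0) {
      selected[cl] <- TRUE
    } else {
      sub <- sum(cl_stab[kids])
      if (cl_stab[cl] >= sub) {
        selected[cl] <- TRUE
        # deselect whole subtree below
        stack <- kids
        while (length(stack) > 0) {
          c2 <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[c2] <- FALSE
          stack <- c(stack, cl_children[[c2]])
        }
      } else {
        cl_stab[cl] <- sub
      }
    }
  }

  # nearest selected ancestor-or-self per condensed cluster
  sel_of <- integer(n_cl)
  for (cl in seq_len(n_cl)) {
    cur <- cl
    hit <- 0L
    while (cur != 0L) {
      if (selected[cur]) { hit <- cur; break }
      cur <- cl_parent[cur]
    }
    sel_of[cl] <- hit
  }
  assign_cl <- sel_of[point_cluster]
  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids) > 0) {
    remap <- match(assign_cl, sel_ids)
    labels[!is.na(remap) & assign_cl > 0] <-
      remap[!is.na(remap) & assign_cl > 0] - 1L
  }
  sizes <- if (length(sel_ids)) tabulate(labels + 1L, nbins = length(sel_ids))
           else integer(0)
  list(labels = labels, n_clusters = length(sel_ids), cluster_sizes = sizes)
}
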