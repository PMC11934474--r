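# Density-based hierarchical clustering (HDBSCAN).
#
# Implemented here from the algorithm: (1) core distance of each point =
# distance to its min_samples-th nearest neighbour (the point itself
# counts); (2) mutual reachability distance mr(a,b) = max(core(a), core(b),
# d(a,b)); (3) minimum spanning tree of the mutual-reachability graph
# (Prim, rows computed on the fly so memory stays O(n)); (4) single-linkage
# hierarchy over the MST edges; (5) condensed tree keeping only components
# of at least min_cluster_size points; (6) cluster selection by excess of
# mass (a cluster is kept when its stability exceeds the summed stability
# of its children); points never captured by a selected cluster are noise.

.core_distances <- function(X, min_samples) {
  n <- nrow(X)
  k <- min(min_samples, n)
  rs <- rowSums(X^2)
  core <- numeric(n)
  chunk <- 1024L
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- outer(rs[i0:i1], rs, "+") - 2 * tcrossprod(X[i0:i1, , drop = FALSE], X)
    d2[d2 < 0] <- 0
    core[i0:i1] <- apply(d2, 1, function(r) sqrt(sort(r, partial = k)[k]))
  }
  core
}

.mst_mutual_reachability <- function(X, core) {
  n <- nrow(X)
  rs <- rowSums(X^2)
  visited <- logical(n)
  mind <- rep(Inf, n)
  from <- integer(n)
  ea <- eb <- integer(n - 1L)
  ed <- numeric(n - 1L)
  cur <- 1L
  visited[1L] <- TRUE
  for (i in seq_len(n - 1L)) {
    d <- sqrt(pmax(rs + rs[cur] - 2 * as.numeric(X %*% X[cur, ]), 0))
    mr <- pmax(d, core, core[cur])
    upd <- !visited & mr < mind
    mind[upd] <- mr[upd]
    from[upd] <- cur
    j <- which.min(mind)        # ties: lowest index, deterministic
    ea[i] <- from[j]; eb[i] <- j; ed[i] <- mind[j]
    visited[j] <- TRUE
    mind[j] <- Inf
    cur <- j
  }
  list(a = ea, b = eb, d = ed)
}

# single-linkage merge tree over MST edges; nodes 1..n are points,
# node n+e is the merge created by the e-th (sorted) edge
.linkage_tree <- function(mst, n) {
  o <- order(mst$d, seq_along(mst$d))
  a <- mst$a[o]; b <- mst$b[o]; d <- mst$d[o]
  uf <- seq_len(n)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  nodeof <- seq_len(n)
  sizes <- c(rep(1L, n), integer(n - 1L))
  childL <- childR <- integer(n - 1L)
  ndist <- numeric(n - 1L)
  for (e in seq_len(n - 1L)) {
    ra <- find(a[e]); rb <- find(b[e])
    node <- n + e
    childL[e] <- nodeof[ra]
    childR[e] <- nodeof[rb]
    ndist[e] <- d[e]
    sizes[node] <- sizes[nodeof[ra]] + sizes[nodeof[rb]]
    uf[ra] <- rb
    nodeof[rb] <- node
  }
  list(childL = childL, childR = childR, dist = ndist, sizes = sizes)
}

.leaves_under <- function(tree, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else {
      e <- v - n
      stack <- c(stack, tree$childL[e], tree$childR[e])
    }
  }
  out
}

.hdbscan <- function(X, min_cluster_size, min_samples) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < max(2L, min_cluster_size))
    return(list(labels = integer(n), n_clusters = 0L))
  core <- .core_distances(X, min_samples)
  tree <- .linkage_tree(.mst_mutual_reachability(X, core), n)
  mcs <- min_cluster_size
  BIG <- 1e12                      # lambda cap for zero-distance merges

  # condensed tree ------------------------------------------------------
  maxcl <- 2L * n
  cl_parent <- integer(maxcl); cl_birth <- numeric(maxcl)
  cl_nbirth <- integer(maxcl); cl_acc <- numeric(maxcl)
  ncl <- 1L
  cl_parent[1] <- 0L; cl_birth[1] <- 0; cl_nbirth[1] <- n
  pt_cluster <- integer(n)
  root_node <- 2L * n - 1L
  stack_node <- root_node; stack_cl <- 1L
  fallout <- function(node, c, lam) {
    pts <- .leaves_under(tree, node, n)
    pt_cluster[pts] <<- c
    cl_acc[c] <<- cl_acc[c] + lam * length(pts)
  }
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]; c <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    e <- v - n
    a <- tree$childL[e]; b <- tree$childR[e]
    lam <- if (tree$dist[e] > 0) 1 / tree$dist[e] else BIG
    sa <- tree$sizes[a]; sb <- tree$sizes[b]
    if (sa >= mcs && sb >= mcs) {            # true split: c dies here
      cl_acc[c] <- cl_acc[c] + lam * (sa + sb)
      for (ch in list(c(a, sa), c(b, sb))) {
        ncl <- ncl + 1L
        cl_parent[ncl] <- c; cl_birth[ncl] <- lam
        cl_nbirth[ncl] <- ch[2]
        stack_node <- c(stack_node, ch[1]); stack_cl <- c(stack_cl, ncl)
      }
    } else if (sa >= mcs) {
      fallout(b, c, lam)
      stack_node <- c(stack_node, a); stack_cl <- c(stack_cl, c)
    } else if (sb >= mcs) {
      fallout(a, c, lam)
      stack_node <- c(stack_node, b); stack_cl <- c(stack_cl, c)
    } else {                                 # c dissolves entirely
      fallout(a, c, lam)
      fallout(b, c, lam)
    }
  }
  cl_parent <- cl_parent[seq_len(ncl)]; cl_birth <- cl_birth[seq_len(ncl)]
  cl_nbirth <- cl_nbirth[seq_len(ncl)]; cl_acc <- cl_acc[seq_len(ncl)]
  stability <- cl_acc - cl_nbirth * cl_birth

  if (ncl == 1L)                             # nothing but the root: all noise
    return(list(labels = integer(n), n_clusters = 0L))

  # excess-of-mass selection --------------------------------------------
  val <- numeric(ncl); selected <- logical(ncl)
  for (c in rev(seq_len(ncl))) {             # creation order: parents first
    kids <- which(cl_parent == c)
    if (length(kids) == 0L) {
      val[c] <- stability[c]; selected[c] <- c != 1L
    } else {
      cs <- sum(val[kids])
      if (c != 1L && stability[c] >= cs) {
        val[c] <- stability[c]; selected[c] <- TRUE
      } else {
        val[c] <- cs; selected[c] <- FALSE
      }
    }
  }
  # a cluster is final iff selected and no selected proper ancestor
  final <- logical(ncl)
  for (c in seq_len(ncl)) {
    if (!selected[c]) next
    anc <- cl_parent[c]; blocked <- FALSE
    while (anc != 0L) {
      if (selected[anc]) { blocked <- TRUE; break }
      anc <- cl_parent[anc]
    }
    final[c] <- !blocked
  }

  # labelling: each point belongs to the final cluster on its parent chain
  owner <- integer(ncl)                      # condensed cluster -> final id
  for (c in seq_len(ncl)) {
    cc <- c
    while (cc != 0L && !final[cc]) cc <- cl_parent[cc]
    owner[c] <- cc
  }
  fin_ids <- which(final)
  labels <- integer(n)
  if (length(fin_ids)) {
    remap <- integer(ncl)
    remap[fin_ids] <- seq_along(fin_ids)
    has <- pt_cluster > 0L & owner[pmax(pt_cluster, 1L)] > 0L
    labels[has] <- remap[owner[pt_cluster[has]]]
  }
  list(labels = labels, n_clusters = length(fin_ids))
}
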