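# Internal mutable simulation state.
#
# The exported API works on immutable `cell_graph` objects; the simulation
# loop needs in-place updates, an O(1) edge-existence test and an incremental
# connected-component tracker. This file provides an environment-backed state
# with a flat logical adjacency vector, a growable edge list, and a union-find
# forest (path halving) for giant-component tracking while edges are only
# added. After deletions (cell death) the forest is rebuilt on demand.

.DEGREE_CAP <- 2L

.st_new <- function(n) {
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$adj <- logical(n * n)   # index (b-1)*n + a, a < b
  st$deg <- integer(n)
  cap <- 256L
  st$ei <- integer(cap)
  st$ej <- integer(cap)
  st$ne <- 0L
  st$parent <- seq_len(n)
  st$csize <- rep(1L, n)
  st$giant <- 1L
  st$uf_valid <- TRUE
  st$n_open <- n           # vertices with degree < cap
  st
}

.st_find <- function(st, x) {
  p <- st$parent
  while (p[x] != x) {
    p[x] <- p[p[x]]
    x <- p[x]
  }
  st$parent <- p
  x
}

# assumes {a,b} eligible (a < b, absent, both degrees < cap)
.st_add <- function(st, a, b) {
  n <- st$n
  st$adj[(b - 1L) * n + a] <- TRUE
  if (st$ne == length(st$ei)) {
    st$ei <- c(st$ei, integer(length(st$ei)))
    st$ej <- c(st$ej, integer(length(st$ej)))
  }
  st$ne <- st$ne + 1L
  st$ei[st$ne] <- a
  st$ej[st$ne] <- b
  da <- st$deg[a] + 1L
  db <- st$deg[b] + 1L
  st$deg[a] <- da
  st$deg[b] <- db
  if (da == .DEGREE_CAP) st$n_open <- st$n_open - 1L
  if (db == .DEGREE_CAP) st$n_open <- st$n_open - 1L
  if (st$uf_valid) {
    ra <- .st_find(st, a)
    rb <- .st_find(st, b)
    if (ra != rb) {
      # union by size
      if (st$csize[ra] < st$csize[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      st$parent[rb] <- ra
      st$csize[ra] <- st$csize[ra] + st$csize[rb]
      if (st$csize[ra] > st$giant) st$giant <- st$csize[ra]
    }
    # ra == rb closes a cycle: component size unchanged
  }
  invisible(st)
}

# full rule check; returns one of the try_add_edge outcome strings
.st_try <- function(st, i, j) {
  if (i == j) return("rejected_self")
  a <- if (i < j) i else j
  b <- if (i < j) j else i
  if (st$adj[(b - 1L) * st$n + a]) return("rejected_exists")
  if (st$deg[a] >= .DEGREE_CAP || st$deg[b] >= .DEGREE_CAP) return("rejected_degree")
  .st_add(st, a, b)
  "added"
}

.st_from_graph <- function(g) {
  st <- .st_new(g$n)
  ne <- nrow(g$edges)
  if (ne > 0L) {
    for (k in seq_len(ne)) .st_add(st, g$edges[k, 1L], g$edges[k, 2L])
  }
  st
}

.st_to_graph <- function(st) {
  idx <- seq_len(st$ne)
  structure(
    list(
      n = st$n,
      edges = matrix(c(st$ei[idx], st$ej[idx]), ncol = 2L,
                     dimnames = list(NULL, c("i", "j"))),
      degree = st$deg
    ),
    class = "cell_graph"
  )
}

# number of unordered eligible pairs: open pairs minus already-linked open pairs
.st_eligible_count <- function(st) {
  no <- st$n_open
  if (no < 2L) return(0)
  e_oo <- 0L
  if (st$ne > 0L) {
    idx <- seq_len(st$ne)
    e_oo <- sum(st$deg[st$ei[idx]] == 1L & st$deg[st$ej[idx]] == 1L)
  }
  no * (no - 1) / 2 - e_oo
}

# all unordered pairs of a vector, vectorized (rows of a 2-column matrix)
.all_pairs <- function(v) {
  k <- length(v)
  first <- rep.int(seq_len(k - 1L), rev(seq_len(k - 1L)))
  second <- sequence(rev(seq_len(k - 1L))) + first
  cbind(v[first], v[second])
}

# all eligible pairs, as a 2-row matrix (may be large; callers guard)
.st_enumerate_eligible <- function(st) {
  open <- which(st$deg < .DEGREE_CAP)
  if (length(open) < 2L) return(matrix(integer(0), nrow = 2L))
  pr <- t(.all_pairs(open))
  keep <- !st$adj[(pr[2L, ] - 1L) * st$n + pr[1L, ]]
  pr[, keep, drop = FALSE]
}

# one pair uniform among eligible pairs; caller guarantees M >= 1
.st_pick_eligible <- function(st, M) {
  n <- st$n
  open <- which(st$deg < .DEGREE_CAP)
  no <- length(open)
  if (no <= 64L || M <= 8) {
    pr <- .st_enumerate_eligible(st)
    k <- if (ncol(pr) == 1L) 1L else sample.int(ncol(pr), 1L)
    return(c(pr[1L, k], pr[2L, k]))
  }
  # rejection among open vertices, filtered to unlinked pairs
  repeat {
    ii <- open[sample.int(no, 64L, replace = TRUE)]
    jj <- open[sample.int(no, 64L, replace = TRUE)]
    keep <- ii != jj
    if (any(keep)) {
      ii <- ii[keep]; jj <- jj[keep]
      a <- pmin(ii, jj); b <- pmax(ii, jj)
      free <- !st$adj[(b - 1L) * n + a]
      if (any(free)) {
        k <- which(free)[1L]
        return(c(a[k], b[k]))
      }
    }
  }
}

# one candidate pair drawn uniformly; at most one edge added (Model 1 rule)
.st_step1 <- function(st) {
  i <- sample.int(st$n, 1L)
  j <- sample.int(st$n, 1L)
  .st_try(st, i, j)
}

# One full Model 2 sweep over all unordered pairs in shuffled order, each
# eligible pair receiving a Bernoulli(p) draw, degrees updated immediately.
# Realised by sampling the Binomial number of successes among the pairs
# eligible at sweep start and resolving that uniformly-chosen candidate set
# in random order with full rule checks. Eligibility only shrinks during a
# sweep (edges are only added), so this is distributionally identical to
# literal pair-by-pair iteration.
.st_sweep2 <- function(st, p) {
  M <- .st_eligible_count(st)
  if (M < 1 || p <= 0) return(0L)
  K <- stats::rbinom(1L, M, p)
  if (K == 0L) return(0L)
  n <- st$n
  open <- which(st$deg < .DEGREE_CAP)
  no <- length(open)
  if (no <= 64L || K > M / 4) {
    pr <- .st_enumerate_eligible(st)
    sel <- sample.int(ncol(pr), K)       # random subset, random order
    aa <- pr[1L, sel]; bb <- pr[2L, sel]
  } else {
    # collect K distinct eligible pairs by rejection among open vertices;
    # first-K distinct uniform draws form a uniform K-subset in uniform order
    keys <- numeric(0)
    aa <- integer(0); bb <- integer(0)
    while (length(keys) < K) {
      B <- max(64L, 2L * (K - length(keys)))
      ii <- open[sample.int(no, B, replace = TRUE)]
      jj <- open[sample.int(no, B, replace = TRUE)]
      keep <- ii != jj
      ii <- ii[keep]; jj <- jj[keep]
      if (!length(ii)) next
      a <- pmin(ii, jj); b <- pmax(ii, jj)
      free <- !st$adj[(b - 1L) * n + a]
      a <- a[free]; b <- b[free]
      if (!length(a)) next
      kk <- (a - 1) * n + b
      new <- !(kk %in% keys) & !duplicated(kk)
      keys <- c(keys, kk[new])
      aa <- c(aa, a[new]); bb <- c(bb, b[new])
    }
    aa <- aa[seq_len(K)]; bb <- bb[seq_len(K)]
  }
  added <- 0L
  for (k in seq_len(K)) {
    a <- aa[k]; b <- bb[k]
    if (st$deg[a] < .DEGREE_CAP && st$deg[b] < .DEGREE_CAP) {
      .st_add(st, a, b)
      added <- added + 1L
    }
  }
  added
}

# remove all edges incident to the given vertices (cell death); the vertex
# slots remain and may re-form edges later
.st_kill <- function(st, dead) {
  if (!length(dead) || st$ne == 0L) return(invisible(st))
  n <- st$n
  idx <- seq_len(st$ne)
  ei <- st$ei[idx]; ej <- st$ej[idx]
  vd <- logical(n); vd[dead] <- TRUE
  drop <- vd[ei] | vd[ej]
  if (!any(drop)) return(invisible(st))
  st$adj[(ej[drop] - 1L) * n + ei[drop]] <- FALSE
  ei <- ei[!drop]; ej <- ej[!drop]
  st$ne <- length(ei)
  st$ei[seq_len(st$ne)] <- ei
  st$ej[seq_len(st$ne)] <- ej
  st$deg <- tabulate(c(ei, ej), nbins = n)
  st$n_open <- sum(st$deg < .DEGREE_CAP)
  st$uf_valid <- FALSE
  invisible(st)
}

# one Model 3 timestep: full Model 2 sweep, then independent deaths
.st_sweep3 <- function(st, p, p_death) {
  .st_sweep2(st, p)
  if (p_death > 0) {
    dead <- which(stats::runif(st$n) < p_death)
    .st_kill(st, dead)
  }
  invisible(st)
}

# component sizes / cycle flags from scratch (used after deletions and for
# snapshots); plain union-find rebuild, O(edges)
.st_snapshot <- function(st) {
  n <- st$n
  idx <- seq_len(st$ne)
  ei <- st$ei[idx]; ej <- st$ej[idx]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in idx) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(n), find, integer(1))
  rid <- match(root, unique(root))
  sizes <- tabulate(rid)
  ecount <- if (st$ne > 0L) tabulate(rid[ei], nbins = length(sizes)) else integer(length(sizes))
  list(
    sizes = as.integer(sizes),
    is_cycle = ecount == sizes,
    edges = matrix(c(ei, ej), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  )
}

.st_giant <- function(st) {
  if (st$uf_valid) return(st$giant)
  max(.st_snapshot(st)$sizes)
}
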