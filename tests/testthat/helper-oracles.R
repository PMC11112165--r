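# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive and share no code with the package internals.

# 6-connected component labelling by breadth-first flood fill
flood_label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(arrayInd(start, d), ncol = 3)
    lab[start] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nbr))) {
        p <- cur + nbr[k, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          queue <- rbind(queue, p)
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition of the foreground?
same_partition <- function(a, b) {
  fa <- a > 0L
  if (!identical(fa, b > 0L)) return(FALSE)
  key_a <- a[fa]
  key_b <- b[fa]
  length(unique(key_a)) == length(unique(key_b)) &&
    !anyDuplicated(unique(cbind(key_a, key_b)))
}

# exhaustive gated assignment: maximal number of links with dist <= gate,
# ties broken by minimum total distance; returns list(row, col)
brute_assignment <- function(d, gate) {
  nr <- nrow(d); nc <- ncol(d)
  best <- list(n = -1L, cost = Inf, row = integer(), col = integer())
  recurse <- function(i, used_cols, rows, cols, cost) {
    if (i > nr) {
      n <- length(rows)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, row = rows, col = cols)
      }
      return(invisible())
    }
    recurse(i + 1L, used_cols, rows, cols, cost)  # leave row i unmatched
    for (j in seq_len(nc)) {
      if (!used_cols[j] && d[i, j] <= gate) {
        used_cols[j] <- TRUE
        recurse(i + 1L, used_cols, c(rows, i), c(cols, j), cost + d[i, j])
        used_cols[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nc), integer(), integer(), 0)
  best[c("row", "col")]
}

# naive average-linkage agglomeration on a distance matrix; returns the
# sequence of merge heights and the k-cluster partition
brute_average_linkage <- function(dmat, k_keep = NULL) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        h <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# membership vector (1..k) from a list-of-index-vectors partition
partition_vector <- function(partition, n) {
  out <- integer(n)
  for (g in seq_along(partition)) out[partition[[g]]] <- g
  out
}

# canonical form so partition labels can be compared irrespective of order
canon_partition <- function(x) match(x, unique(x))
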