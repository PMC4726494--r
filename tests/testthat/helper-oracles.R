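# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Exact infinite-sites sample probability by exhaustive recursion over
# ancestral configurations (memoized). Haplotypes are site-index sets with
# multiplicities; the recursion enumerates every admissible most-recent
# event (coalescence of identical haplotypes; removal of a private singleton
# mutation) with its combinatorial coefficient.
exactSampleProb <- local({
  memo <- new.env(parent = emptyenv())
  canon <- function(hap, mult) {
    o <- order(vapply(hap, paste, character(1L), collapse = ","), mult)
    paste(vapply(o, function(i)
      paste0("{", paste(hap[[i]], collapse = ","), "}x", mult[i]),
      character(1L)), collapse = ";")
  }
  f <- function(hap, mult, theta) {
    keep <- mult > 0
    hap <- hap[keep]; mult <- mult[keep]
    n <- sum(mult)
    if (n == 1L) return(if (length(hap[[1L]]) == 0L) 1 else 0)
    key <- paste0(canon(hap, mult), "|", theta)
    if (!is.null(memo[[key]])) return(memo[[key]])
    D <- n * (n - 1 + theta) / 2
    tot <- 0
    for (i in seq_along(hap)) {
      if (mult[i] >= 2L) {
        m2 <- mult; m2[i] <- m2[i] - 1L
        tot <- tot + mult[i] * (mult[i] - 1) / 2 * f(hap, m2, theta)
      }
      if (mult[i] == 1L) {
        for (s in hap[[i]]) {
          shared <- any(vapply(seq_along(hap), function(j)
            j != i && mult[j] > 0L && s %in% hap[[j]], logical(1L)))
          if (shared) next
          red <- setdiff(hap[[i]], s)
          j <- which(vapply(seq_along(hap), function(j)
            j != i && mult[j] > 0L && setequal(hap[[j]], red), logical(1L)))
          if (length(j)) {
            m2 <- mult; m2[i] <- 0L; m2[j] <- m2[j] + 1L
            tot <- tot + theta / 2 * (mult[j] + 1) * f(hap, m2, theta)
          } else {
            h2 <- hap; h2[[i]] <- red
            tot <- tot + theta / 2 * f(h2, mult, theta)
          }
        }
      }
    }
    memo[[key]] <- tot / D
    tot / D
  }
  function(sample, theta) {
    m <- sample@siteMatrix
    hap <- lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1L))
    f(hap, as.numeric(sample@multiplicities), theta)
  }
})

# All distinct haplotype configurations with n sequences and S segregating
# sites, up to column (sequence) relabeling: every assignment of each site's
# carrier set, filtered to four-gamete-compatible matrices and deduplicated
# by the minimal representative over column permutations.
enumerateConfigs <- function(n, S) {
  if (S == 0L)
    return(list(haplotypeSample(matrix(integer(0), 0L, n))))
  carrierSets <- lapply(seq_len(2^n - 2L), function(code) {
    as.integer(intToBits(code)[seq_len(n)])
  })
  carrierSets <- Filter(function(x) sum(x) >= 1L && sum(x) <= n - 1L,
                        carrierSets)
  idx <- do.call(expand.grid, rep(list(seq_along(carrierSets)), S))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  colPerms <- perms(seq_len(n))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (r in seq_len(nrow(idx))) {
    m <- do.call(rbind, carrierSets[as.integer(idx[r, ])])
    keys <- vapply(colPerms, function(p) {
      mm <- m[, p, drop = FALSE]
      paste(sort(apply(mm, 1L, paste, collapse = "")), collapse = "|")
    }, character(1L))
    key <- min(keys)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    s <- tryCatch(haplotypeSample(m), error = function(e) NULL)
    if (is.null(s)) next
    if (!isTRUE(as.logical(checkInfiniteSites(s)))) next
    out[[length(out) + 1L]] <- s
  }
  out
}

# JC69 likelihood oracle through numeric matrix exponentials of the rate
# matrix (eigen-decomposition), summing over internal states site by site.
jcOracleLoglik <- function(geneTree, bases, scalar = 1) {
  Q <- matrix(1 / 3, 4L, 4L); diag(Q) <- -1
  eg <- eigen(Q)
  Pt <- function(t) {
    re <- eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors)
    pmax(Re(re), 0)
  }
  nNode <- length(geneTree$parent)
  children <- lapply(seq_len(nNode), function(v) which(geneTree$parent == v))
  lik <- function(v, site) {
    if (v <= geneTree$nTip) {
      out <- numeric(4L); out[bases[v, site] + 1L] <- 1
      return(out)
    }
    out <- rep(1, 4L)
    for (ch in children[[v]]) {
      t <- (geneTree$time[v] - geneTree$time[ch]) * scalar
      out <- out * as.vector(Pt(t) %*% lik(ch, site))
    }
    out
  }
  sum(vapply(seq_len(ncol(bases)), function(s)
    log(sum(0.25 * lik(geneTree$root, s))), numeric(1L)))
}

# random ultrametric species tree (pure-birth shape) with a fixed root age
randomChronogram <- function(ntip, rootAge, seed) {
  set.seed(seed)
  tr <- ape::rphylo(ntip, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * rootAge /
    max(ape::node.depth.edgelength(tr))
  tr
}
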