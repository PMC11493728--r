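# Independent oracles, deliberately implemented apart from the package
# internals: a plain-R Gotoh dynamic program with the same scoring and
# tie-break conventions (match +1, mismatch -1, gap open -2, extend -1;
# diagonal > deletion > insertion; close gaps as early as possible), and a
# brute-force double-summation E-test.

oracleAlign <- function(read, ref) {
  n <- nchar(ref); m <- nchar(read)
  ra <- strsplit(ref, "")[[1]]; rd <- strsplit(read, "")[[1]]
  NEG <- -1e8
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in read (deletion, consumes ref)
  Y <- matrix(NEG, n + 1, m + 1) # gap in ref (insertion, consumes read)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(2 + (i - 2))
  for (j in 2:(m + 1)) Y[1, j] <- -(2 + (j - 2))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (ra[i - 1] == rd[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - 2, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 2, Y[i, j - 1] - 1)
    }
  }
  sc <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which(sc == max(sc))[1] # prefer M, then X, then Y on ties
  i <- n; j <- m
  nSub <- dels <- ins <- 0L
  delPos <- integer(); insBnd <- integer()
  while (i > 0 || j > 0) {
    if (state == 1) {
      if (ra[i] != rd[j]) nSub <- nSub + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      nxt <- which(prev == max(prev))[1]
      i <- i - 1; j <- j - 1
      state <- nxt
      if (i == 0 && j == 0) break
      if (i == 0) state <- 3
      if (j == 0) state <- 2
    } else if (state == 2) {
      dels <- dels + 1L
      delPos <- c(delPos, i) # 1-based ref position deleted
      cur <- X[i + 1, j + 1]
      state <- if (M[i, j + 1] - 2 == cur) 1 else 2
      i <- i - 1
      if (i == 0 && j > 0) state <- 3
      if (i == 0 && j == 0) break
    } else {
      ins <- ins + 1L
      insBnd <- c(insBnd, i) # inserted before 0-based ref position i
      cur <- Y[i + 1, j + 1]
      state <- if (M[i + 1, j] - 2 == cur) 1 else 3
      j <- j - 1
      if (j == 0 && i > 0) state <- 2
      if (i == 0 && j == 0) break
    }
  }
  list(score = max(sc), nSub = nSub, delBases = dels, insBases = ins,
       delPos = sort(delPos), insBoundaries = sort(insBnd))
}

oracleETest <- function(c0, t0, c1, t1) {
  lam <- (c0 + c1) / (t0 + t1)
  if (lam == 0) return(1)
  se <- sqrt(lam * (1 / t0 + 1 / t1))
  tobs <- (c1 / t1 - c0 / t0) / se
  if (abs(tobs) < 1e-12) return(1)
  m0 <- lam * t0; m1 <- lam * t1
  y0 <- 0:ceiling(m0 + max(10 * sqrt(m0), 50))
  y1 <- 0:ceiling(m1 + max(10 * sqrt(m1), 50))
  TT <- outer(y0 / t0, y1 / t1, function(a, b) (b - a) / se)
  W <- outer(dpois(y0, m0), dpois(y1, m1))
  sum(W[abs(TT) >= abs(tobs) * (1 - 1e-10)])
}

# random read mutator independent of the package generator (for alignment
# oracle tests): applies a fixed number of substitutions / 1-3 bp indels
randomMutate <- function(seq, nSub = 0, nDel = 0, nIns = 0) {
  ch <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (nSub > 0) {
    pos <- sample(length(ch), nSub)
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
  }
  if (nDel > 0) {
    for (k in seq_len(nDel)) {
      len <- sample(1:3, 1)
      p <- sample(length(ch) - len, 1)
      ch <- ch[-(p:(p + len - 1))]
    }
  }
  if (nIns > 0) {
    for (k in seq_len(nIns)) {
      len <- sample(1:3, 1)
      p <- sample(length(ch), 1)
      ch <- append(ch, sample(bases, len, replace = TRUE), after = p)
    }
  }
  paste(ch, collapse = "")
}
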