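# Independent alignment oracles.
#
# oracle_align: top-down memoised recursion over (read index, ref index,
# gap state) written in plain R, independent of the package's iterative
# Gotoh implementation. Same optimisation problem: read global, reference
# end gaps free, gap of length L costs gap_open + L*gap_extend, preference
# diagonal > insertion > deletion on ties.
#
# enum_align: true exhaustive enumeration of every alignment (all move
# sequences from every free start), tractable only for tiny inputs; returns
# the optimal score and ALL optimal op multisets.

oracle_align <- function(read, ref, match = 1, mismatch = -1,
                         gap_open = -4, gap_extend = -1) {
  n <- nchar(read)
  m <- nchar(ref)
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  go <- gap_open + gap_extend
  ge <- gap_extend
  memo <- new.env(parent = emptyenv())

  # best score for read[i..n) with ref cursor j (0-based counts consumed),
  # state: 0 = diag/start, 1 = in insertion, 2 = in deletion
  sc <- function(i, j, state) {
    if (i == n) return(0)  # free reference suffix
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (j < m) {
      s <- if (rd[i + 1] == rf[j + 1]) match else mismatch
      best <- max(best, s + sc(i + 1, j + 1, 0))
    }
    best <- max(best, (if (state == 1) ge else go) + sc(i + 1, j, 1))
    if (j < m) {
      best <- max(best, (if (state == 2) ge else go) + sc(i, j + 1, 2))
    }
    memo[[key]] <- best
    best
  }

  starts <- vapply(0:m, function(j0) sc(0, j0, 0), numeric(1))
  score <- max(starts)
  j <- (which(starts == score)[1]) - 1L  # smallest free-prefix start on ties

  # reconstruct one optimal path with preference diag > ins > del
  ops <- character(0)
  i <- 0L
  state <- 0L
  while (i < n) {
    cur <- sc(i, j, state)
    if (j < m) {
      s <- if (rd[i + 1] == rf[j + 1]) match else mismatch
      if (isTRUE(all.equal(cur, s + sc(i + 1L, j + 1L, 0L)))) {
        ops <- c(ops, if (rd[i + 1] == rf[j + 1]) "match" else "mismatch")
        i <- i + 1L; j <- j + 1L; state <- 0L
        next
      }
    }
    ins_cost <- if (state == 1L) ge else go
    if (isTRUE(all.equal(cur, ins_cost + sc(i + 1L, j, 1L)))) {
      ops <- c(ops, "ins")
      i <- i + 1L; state <- 1L
      next
    }
    ops <- c(ops, "del")
    j <- j + 1L; state <- 2L
  }
  list(score = score, ops = ops)
}

enum_align <- function(read, ref, match = 1, mismatch = -1,
                       gap_open = -4, gap_extend = -1) {
  n <- nchar(read)
  m <- nchar(ref)
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  go <- gap_open + gap_extend
  ge <- gap_extend

  results <- list()
  walk <- function(i, j, state, score, ops) {
    if (i == n) {  # free suffix: stop here
      results[[length(results) + 1L]] <<- list(score = score, ops = ops)
      return(invisible())
    }
    if (j < m) {
      s <- if (rd[i + 1] == rf[j + 1]) match else mismatch
      walk(i + 1L, j + 1L, 0L, score + s,
           c(ops, if (rd[i + 1] == rf[j + 1]) "match" else "mismatch"))
    }
    walk(i + 1L, j, 1L, score + (if (state == 1L) ge else go), c(ops, "ins"))
    if (j < m) {
      walk(i, j + 1L, 2L, score + (if (state == 2L) ge else go), c(ops, "del"))
    }
  }
  for (j0 in 0:m) walk(0L, j0, 0L, 0, character(0))

  scores <- vapply(results, `[[`, numeric(1), "score")
  best <- max(scores)
  multisets <- unique(lapply(results[scores == best], function(r) {
    tab <- table(factor(r$ops, levels = c("match", "mismatch", "ins", "del")))
    as.integer(tab)
  }))
  list(score = best, multisets = multisets)
}

# op multiset of a package alignment, as counts of match/mismatch/ins/del bases
aln_multiset <- function(aln) {
  ops <- rep(aln$ops$op, aln$ops$length)
  as.integer(table(factor(ops, levels = c("match", "mismatch", "ins", "del"))))
}

# Check that an alignment's ops are internally consistent: coordinates
# advance correctly, match/mismatch runs agree with the sequences, every
# read base is consumed, and the score recomputed from the runs (affine
# costs) equals the reported score. A valid op list whose recomputed score
# equals the independent oracle's optimum is, by construction, one of the
# optimal alignments an exhaustive enumeration would produce.
validate_alignment <- function(aln, match = 1, mismatch = -1,
                               gap_open = -4, gap_extend = -1) {
  rp <- aln$ref_start
  qp <- 0L
  score <- 0
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[k]
    len <- aln$ops$length[k]
    if (aln$ops$ref_pos[k] != rp || aln$ops$read_pos[k] != qp) return(FALSE)
    rseg <- substr(aln$ref, rp + 1L, rp + len)
    qseg <- substr(aln$read, qp + 1L, qp + len)
    if (op == "match") {
      if (rseg != qseg) return(FALSE)
      score <- score + match * len
      rp <- rp + len; qp <- qp + len
    } else if (op == "mismatch") {
      if (any(strsplit(rseg, "")[[1]] == strsplit(qseg, "")[[1]])) return(FALSE)
      score <- score + mismatch * len
      rp <- rp + len; qp <- qp + len
    } else if (op == "ins") {
      score <- score + gap_open + gap_extend * len
      qp <- qp + len
    } else if (op == "del") {
      score <- score + gap_open + gap_extend * len
      rp <- rp + len
    } else return(FALSE)
  }
  qp == nchar(aln$read) && rp == aln$ref_end && score == aln$score
}
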