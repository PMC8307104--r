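# Template-constrained cloverleaf folding for mitochondrial tRNAs.
#
# The fold is a search over arm-length combinations within canonical bounds
# (acceptor stem fixed at 7 pairs; DHU stem 0 or 2-4; anticodon stem 3-6;
# TpsiC stem 3-6; variable loop 3-9 nt), anchored at the annotated
# anticodon, which sits at the centre of a 7-nt anticodon loop. Candidate
# decompositions are scored 2 per Watson-Crick pair, 1 per G-U wobble and -1
# per mismatched stem position; this is a structural template search, not
# free-energy minimisation. A DHU stem of length 0 yields the
# tRNA-Ser(AGN)-type topology in which the DHU arm is replaced by a loop.

DEFAULT_TRNA_BOUNDS <- list(
  acceptor = 7L, dhu_stem = 2:4, dhu_loop = 3:10, ac_stem = 3:6,
  tpsic_stem = 3:6, tpsic_loop = 3:9, var_loop = 3:9,
  conn1 = 1:3, conn2 = 0:2, tail = 0:2, dhu_absent_span = 4:12
)

# pair scores, rows/cols in BASES order (A C G T)
pair_score_matrix <- function() {
  if (!is.null(.mc_cache$pairmat)) return(.mc_cache$pairmat)
  m <- matrix(-1, 4L, 4L, dimnames = list(BASES, BASES))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 2
  m["G", "T"] <- m["T", "G"] <- 1
  .mc_cache$pairmat <- m
  m
}

stem_score <- function(chars, i5, i3) {
  if (!length(i5)) return(0)
  m <- pair_score_matrix()
  a <- match(chars[i5], BASES); b <- match(chars[i3], BASES)
  ok <- !is.na(a) & !is.na(b)
  sum(m[cbind(a[ok], b[ok])]) - sum(!ok)
}

# index helpers: a stem of length k pairing span [s5..s5+k-1] against the
# reverse of [e3-k+1..e3]
stem_pairs <- function(s5, e3, k) {
  if (k == 0L) return(matrix(integer(0), 0L, 2L))
  cbind(s5 + 0:(k - 1L), e3 - 0:(k - 1L))
}

#' Fold a tRNA sequence into a cloverleaf
#'
#' @param seq tRNA gene sequence (reading direction), 50-100 nt.
#' @param anticodon The 3-letter anticodon; must occur in `seq` and anchors
#'   the anticodon loop.
#' @param relax_ac_loop Allow a 9-nt anticodon loop in addition to the
#'   canonical 7 nt (off by default; covers the rare long-loop variants).
#' @param bounds Template bounds, see `DEFAULT_TRNA_BOUNDS`; all entries
#'   overridable.
#' @return Object of class `cloverleaf`: arm-resolved index spans, stem pair
#'   index matrices, the anticodon position, arm lengths
#'   `c(acceptor, dhu, ac, tpsic)`, total score, and a dot-bracket string.
#' @export
fold_trna <- function(seq, anticodon, relax_ac_loop = FALSE,
                      bounds = list()) {
  seq <- toupper(seq); anticodon <- toupper(anticodon)
  L <- nchar(seq)
  if (L < 50L || L > 100L)
    stop("too-short error: tRNA length outside 50-100 nt", call. = FALSE)
  b <- utils::modifyList(DEFAULT_TRNA_BOUNDS, bounds)
  chars <- seq_chars(seq)
  anchors <- as.integer(gregexpr(anticodon, seq, fixed = TRUE)[[1L]])
  if (anchors[1L] == -1L)
    stop("anchor error: anticodon not found in sequence", call. = FALSE)
  ac_loops <- if (relax_ac_loop) c(7L, 9L) else 7L

  best <- NULL
  consider <- function(cand) {
    # deterministic preference: score, acceptor score, DHU length 4,
    # variable loop 4-5, longer anticodon stem, then enumeration order
    # (first wins ties)
    key <- c(cand$score, cand$acc_score, as.integer(cand$d == 4L),
             as.integer(cand$v %in% 4:5), cand$a)
    if (is.null(best)) {
      cand$key <- key
      best <<- cand
      return(invisible())
    }
    bk <- best$key
    for (lvl in seq_along(key)) {
      if (key[lvl] > bk[lvl]) {
        cand$key <- key
        best <<- cand
        return(invisible())
      }
      if (key[lvl] < bk[lvl]) return(invisible())
    }
    invisible()
  }

  for (q in anchors) for (al in ac_loops) {
    pre <- (al - 3L) %/% 2L
    loop_start <- q - pre; loop_end <- q + 2L + pre
    for (a in b$ac_stem) {
      ac5_start <- loop_start - a
      rem_left <- ac5_start - 8L            # c1 + dhu arm + c2
      if (rem_left < 0L) next
      ac_sc <- stem_score(chars,
                          ac5_start + 0:(a - 1L),
                          (loop_end + a) - 0:(a - 1L))
      # left-side candidates: list(d, c1, loop_d, c2, score)
      lefts <- list()
      if (rem_left %in% b$dhu_absent_span)
        lefts[[length(lefts) + 1L]] <-
          list(d = 0L, c1 = rem_left, loop_d = 0L, c2 = 0L, sc = 0)
      for (d in b$dhu_stem) for (c1 in b$conn1) for (c2 in b$conn2) {
        loop_d <- rem_left - 2L * d - c1 - c2
        if (!(loop_d %in% b$dhu_loop)) next
        d5 <- 8L + c1
        arm_end <- d5 + 2L * d + loop_d - 1L
        sc <- stem_score(chars, d5 + 0:(d - 1L), arm_end - 0:(d - 1L))
        lefts[[length(lefts) + 1L]] <-
          list(d = d, c1 = c1, loop_d = loop_d, c2 = c2, sc = sc)
      }
      if (!length(lefts)) next
      # right-side candidates
      r0 <- loop_end + a                     # end of anticodon stem 3'
      rights <- list()
      for (e in b$tail) {
        acc3_end <- L - e
        acc_sc <- stem_score(chars, 1:7, acc3_end - 0:6)
        R <- acc3_end - 7L - r0              # v + 2t + loop_t
        if (R < 0L) next
        for (t in b$tpsic_stem) for (v in b$var_loop) {
          loop_t <- R - v - 2L * t
          if (!(loop_t %in% b$tpsic_loop)) next
          t5 <- r0 + v + 1L
          arm_end <- t5 + 2L * t + loop_t - 1L
          sc <- stem_score(chars, t5 + 0:(t - 1L), arm_end - 0:(t - 1L))
          rights[[length(rights) + 1L]] <-
            list(e = e, t = t, v = v, loop_t = loop_t, sc = sc,
                 acc_sc = acc_sc)
        }
      }
      for (lf in lefts) for (rt in rights)
        consider(list(q = q, al = al, a = a, d = lf$d, c1 = lf$c1,
                      loop_d = lf$loop_d, c2 = lf$c2, t = rt$t, v = rt$v,
                      loop_t = rt$loop_t, e = rt$e,
                      acc_score = rt$acc_sc,
                      score = rt$acc_sc + lf$sc + ac_sc + rt$sc))
    }
  }
  if (is.null(best))
    stop("fold-failure error: no template-consistent decomposition",
         call. = FALSE)
  build_cloverleaf(seq, best)
}

build_cloverleaf <- function(seq, cand) {
  L <- nchar(seq)
  with(cand, {
    pre <- (al - 3L) %/% 2L
    loop_start <- q - pre; loop_end <- q + 2L + pre
    acc3_end <- L - e
    acc_pairs <- stem_pairs(1L, acc3_end, 7L)
    d5 <- 8L + c1
    dhu_span <- if (d == 0L) integer(0) else d5:(d5 + 2L * d + loop_d - 1L)
    dhu_pairs <- if (d == 0L) stem_pairs(0L, 0L, 0L) else
      stem_pairs(d5, d5 + 2L * d + loop_d - 1L, d)
    ac5 <- loop_start - a
    ac_pairs <- stem_pairs(ac5, loop_end + a, a)
    t5 <- loop_end + a + v + 1L
    t_end <- t5 + 2L * t + loop_t - 1L
    t_pairs <- stem_pairs(t5, t_end, t)
    db <- rep(".", L)
    for (p in list(acc_pairs, dhu_pairs, ac_pairs, t_pairs)) {
      db[p[, 1L]] <- "("; db[p[, 2L]] <- ")"
    }
    structure(list(
      length = L,
      anticodon_position = q,
      ac_loop_span = c(loop_start, loop_end),
      acceptor_pairs = acc_pairs,
      dhu_pairs = dhu_pairs,
      dhu_loop_span = if (d > 0L)
        c(d5 + d, d5 + d + loop_d - 1L) else
        if (c1 > 0L) c(8L, 8L + c1 - 1L) else c(NA_integer_, NA_integer_),
      anticodon_pairs = ac_pairs,
      tpsic_pairs = t_pairs,
      tpsic_loop_span = c(t5 + t, t5 + t + loop_t - 1L),
      var_loop_span = if (v > 0L)
        c(loop_end + a + 1L, loop_end + a + v) else c(NA_integer_, NA_integer_),
      arm_lengths = c(acceptor = 7L, dhu = d, ac = a, tpsic = t),
      var_loop_length = v,
      dhu_present = d > 0L,
      score = score,
      dot_bracket = paste(db, collapse = "")
    ), class = "cloverleaf")
  })
}

#' @export
print.cloverleaf <- function(x, ...) {
  al <- x$arm_lengths
  cat(sprintf(
    "<cloverleaf> %d nt; stems acceptor %d, DHU %s, anticodon %d, TpsiC %d; score %d\n",
    x$length, al[["acceptor"]],
    if (x$dhu_present) al[["dhu"]] else "absent", al[["ac"]], al[["tpsic"]],
    x$score))
  cat(x$dot_bracket, "\n")
  invisible(x)
}

#' Classify the stem pairs of a folded tRNA
#'
#' @param structure A `cloverleaf` from [fold_trna()].
#' @param seq The folded sequence.
#' @return Object of class `pair_classification`: counts `watson_crick`,
#'   `gu_wobble`, and a data frame `mismatches` (5'/3' positions and the
#'   pair type, e.g. "A-G").
#' @export
classify_pairs <- function(structure, seq) {
  seq <- toupper(seq)
  chars <- seq_chars(seq)
  pairs <- rbind(structure$acceptor_pairs, structure$dhu_pairs,
                 structure$anticodon_pairs, structure$tpsic_pairs)
  if (any(pairs > nchar(seq)))
    stop("structure error: pair index out of range", call. = FALSE)
  b5 <- chars[pairs[, 1L]]; b3 <- chars[pairs[, 2L]]
  wc <- (b5 == "A" & b3 == "T") | (b5 == "T" & b3 == "A") |
    (b5 == "G" & b3 == "C") | (b5 == "C" & b3 == "G")
  gu <- (b5 == "G" & b3 == "T") | (b5 == "T" & b3 == "G")
  mis <- !(wc | gu)
  out <- list(
    watson_crick = sum(wc), gu_wobble = sum(gu),
    mismatches = data.frame(
      pos5 = pairs[mis, 1L], pos3 = pairs[mis, 2L],
      type = if (any(mis)) paste0(b5[mis], "-", b3[mis]) else character(0),
      stringsAsFactors = FALSE),
    total = nrow(pairs))
  class(out) <- "pair_classification"
  out
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("<pair_classification> %d pairs: %d Watson-Crick, %d G-U, %d mismatches\n",
              x$total, x$watson_crick, x$gu_wobble, nrow(x$mismatches)))
  invisible(x)
}

# label every position of a fold with its structural role (arm-relative)
structure_roles <- function(structure) {
  L <- structure$length
  roles <- rep(NA_character_, L)
  tag <- function(idx, prefix) {
    if (!length(idx) || anyNA(idx)) return()
    roles[idx] <<- paste0(prefix, ".", seq_along(idx))
  }
  span <- function(s) if (anyNA(s)) integer(0) else s[1L]:s[2L]
  tag(structure$acceptor_pairs[, 1L], "acc5")
  tag(rev(structure$acceptor_pairs[, 2L]), "acc3")
  tag(structure$dhu_pairs[, 1L], "dhu5")
  tag(rev(structure$dhu_pairs[, 2L]), "dhu3")
  tag(span(structure$dhu_loop_span), "dhuL")
  tag(structure$anticodon_pairs[, 1L], "ac5")
  tag(rev(structure$anticodon_pairs[, 2L]), "ac3")
  tag(span(structure$ac_loop_span), "acL")
  tag(span(structure$var_loop_span), "varL")
  tag(structure$tpsic_pairs[, 1L], "t5")
  tag(rev(structure$tpsic_pairs[, 2L]), "t3")
  tag(span(structure$tpsic_loop_span), "tL")
  roles[is.na(roles)] <- paste0("conn.", seq_len(sum(is.na(roles))))
  roles
}

#' Position-wise conservation of one tRNA across species
#'
#' Compares structure-anchored (arm-relative) positions, not raw indices, so
#' species with different arm or loop lengths remain comparable. A position
#' (role) is conserved when it exists in every species with an identical
#' nucleotide.
#'
#' @param structures Named list of `cloverleaf` folds, one per species.
#' @param seqs Matching named list/vector of sequences.
#' @return Data frame with columns `role`, `conserved` (logical).
#' @export
compare_structures <- function(structures, seqs) {
  stopifnot(length(structures) == length(seqs), length(structures) >= 2L)
  per <- Map(function(st, sq) {
    r <- structure_roles(st)
    setNames(seq_chars(toupper(sq)), r)
  }, structures, seqs)
  roles <- unique(unlist(lapply(per, names)))
  conserved <- vapply(roles, function(ro) {
    vals <- vapply(per, function(x)
      if (ro %in% names(x)) x[[ro]] else NA_character_, "")
    !anyNA(vals) && length(unique(vals)) == 1L
  }, TRUE)
  data.frame(role = roles, conserved = unname(conserved),
             stringsAsFactors = FALSE)
}

#' Design a template-consistent tRNA sequence with perfect stems
#'
#' Builds a cloverleaf-foldable sequence with fully Watson-Crick-paired
#' stems of the requested lengths and random loop/connector bases — the
#' generator used by the simulator and by fold-recovery checks.
#'
#' @param anticodon 3-letter anticodon placed at the centre of the 7-nt
#'   anticodon loop.
#' @param dhu,ac,tpsic Stem lengths (DHU may be 0 for the Ser(AGN)
#'   topology).
#' @param dhu_loop,tpsic_loop,var_loop,conn1,conn2,tail Loop/connector
#'   lengths.
#' @param total_length Optional target length; when given, the variable and
#'   TpsiC loop lengths are adjusted within template bounds to hit it
#'   exactly (error when infeasible).
#' @param at A+T fraction used when drawing random bases (loops, connectors
#'   and 5' stem strands; complementary strands inherit the same A+T
#'   content).
#' @param seal When TRUE (default), unpaired regions (loops, connectors,
#'   tail) are drawn from the non-self-pairing alphabet \{A, C\}, so no stem
#'   can be extended or relocated into them: the designed decomposition is
#'   the unique score-optimal fold and the generating arm lengths are
#'   identifiable. With `seal = FALSE` loops are fully random and a
#'   better-scoring alternative fold may exist.
#' @return List with `seq` and the generating `arm_lengths`.
#' @export
design_trna <- function(anticodon, dhu = 4L, ac = 5L, tpsic = 5L,
                        dhu_loop = 7L, tpsic_loop = 7L, var_loop = 5L,
                        conn1 = 2L, conn2 = 1L, tail = 1L,
                        total_length = NULL, at = 0.5, seal = TRUE) {
  anticodon <- toupper(anticodon)
  stopifnot(nchar(anticodon) == 3L)
  base_len <- function(vl, tl)
    14L + conn1 + (if (dhu > 0L) 2L * dhu + dhu_loop else 0L) + conn2 +
      2L * ac + 7L + vl + 2L * tpsic + tl + tail
  if (!is.null(total_length)) {
    found <- FALSE
    for (vl in 3:9) for (tl in 3:9)
      if (!found && base_len(vl, tl) == total_length) {
        var_loop <- vl; tpsic_loop <- tl; found <- TRUE
      }
    if (!found)
      stop("generation error: length infeasible for these arms",
           call. = FALSE)
  }
  rnd <- function(n) if (n > 0L)
    paste(sample(BASES, n, replace = TRUE,
                 prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
          collapse = "") else ""
  # unpaired regions: A/C cannot pair with each other (no WC, no G-U)
  unp <- if (seal) function(n) {
    if (n > 0L) paste(sample(c("A", "C"), n, replace = TRUE,
                             prob = c(at, 1 - at)), collapse = "") else ""
  } else rnd
  acc5 <- rnd(7L); d5 <- rnd(dhu); ac5 <- rnd(ac); t5 <- rnd(tpsic)
  dhu_arm <- if (dhu > 0L) paste0(d5, unp(dhu_loop), rev_comp(d5)) else ""
  ac_loop <- paste0(unp(2L), anticodon, unp(2L))
  seq <- paste0(acc5, unp(conn1), dhu_arm, unp(conn2),
                ac5, ac_loop, rev_comp(ac5), unp(var_loop),
                t5, unp(tpsic_loop), rev_comp(t5), rev_comp(acc5),
                unp(tail))
  list(seq = seq,
       arm_lengths = c(acceptor = 7L, dhu = as.integer(dhu),
                       ac = as.integer(ac), tpsic = as.integer(tpsic)),
       var_loop_length = as.integer(var_loop))
}
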