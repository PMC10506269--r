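#' Position weight matrix
#'
#' Per-position base probabilities of a sequence motif, rows in the fixed
#' channel order (A, C, G, T).
#'
#' @param probs m x 4 matrix of probabilities, rows summing to 1.
#' @param name class label the motif stands for.
#' @return a `pwm` object.
#' @export
pwm <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stopf("a PWM needs 4 columns (A,C,G,T)")
  if (nrow(probs) < 4L) stopf("motif length must be >= 4, got %d", nrow(probs))
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stopf("PWM rows must be probability vectors summing to 1")
  }
  colnames(probs) <- DNA_BASES
  structure(list(name = as.character(name), probs = probs), class = "pwm")
}

#' Consensus sequence of a PWM
#' @param x a [pwm()].
#' @return character string of the per-position argmax bases.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[max.col(x$probs, ties.method = "first")], collapse = "")
}

#' Mean per-position information content of a PWM (bits)
#' @param x a [pwm()].
#' @return scalar in [0, 2].
#' @export
pwm_information <- function(x) {
  stopifnot(inherits(x, "pwm"))
  p <- x$probs
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  mean(2 - h)
}

#' Generate well-separated default motifs
#'
#' Draws `C` random consensus sequences whose pairwise Hamming distance is at
#' least `m / 2` (rejection sampling with a bounded retry budget) and softens
#' each into a PWM: position j puts probability `exp(s) / (exp(s) + 3)` on the
#' consensus base and `1 / (exp(s) + 3)` elsewhere, so the per-position
#' information content grows monotonically with the sharpness `s` and the
#' `s -> Inf` limit is the consensus-only motif.
#'
#' @param C number of motifs (classes).
#' @param m motif length, >= 4.
#' @param sharpness concentration `s >= 0`.
#' @param seed integer seed.
#' @param max_tries rejection budget for the distance constraint.
#' @return list of `C` [pwm()] objects named `TF1..TFC`.
#' @export
make_default_pwms <- function(C, m = 8L, sharpness = 4, seed = 1L, max_tries = 1000L) {
  if (!is_count(C)) stopf("C must be a positive integer")
  if (!is_count(m, min = 4L)) stopf("motif length m must be an integer >= 4")
  if (!is.numeric(sharpness) || sharpness < 0) stopf("sharpness must be >= 0")
  consensus <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      cons <- matrix(sample.int(4L, C * m, replace = TRUE), C, m)
      ok <- TRUE
      if (C > 1L) {
        for (a in seq_len(C - 1L)) {
          for (b in (a + 1L):C) {
            if (sum(cons[a, ] != cons[b, ]) < m / 2) { ok <- FALSE; break }
          }
          if (!ok) break
        }
      }
      if (ok) break
    }
    if (!ok) stopf("could not draw %d consensus motifs with pairwise distance >= %g in %d tries",
                   C, m / 2, max_tries)
    cons
  })
  p_hi <- exp(sharpness) / (exp(sharpness) + 3)
  p_lo <- 1 / (exp(sharpness) + 3)
  lapply(seq_len(C), function(cl) {
    probs <- matrix(p_lo, m, 4L)
    probs[cbind(seq_len(m), consensus[cl, ])] <- p_hi
    pwm(probs, name = paste0("TF", cl))
  })
}

#' Simulation configuration
#'
#' The stated world the generator emulates: fixed-length random-background
#' DNA, multi-label class membership drawn per class as Bernoulli(prevalence),
#' and one PWM sample embedded at a uniform random non-overlapping position
#' for every positive label. Labels record embeddings exactly (no label
#' noise).
#'
#' @param n number of sequences.
#' @param length sequence length L (>= max motif length). 100 is the test
#'   scale; 1000 matches the real ChIP-seq windows.
#' @param pwms list of [pwm()] objects, one per class.
#' @param prevalence per-class positive probability in (0, 1).
#' @param background base composition over (A, C, G, T); default uniform.
#' @param embed_per_positive motif instances embedded per positive label.
#' @param revcomp also embed reverse-complement instances (each instance is
#'   flipped with probability 1/2).
#' @param seed mandatory integer seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(n, length = 100L, pwms, prevalence = 0.3,
                       background = rep(0.25, 4), embed_per_positive = 1L,
                       revcomp = FALSE, seed) {
  if (missing(seed)) stopf("seed is mandatory for a simulation")
  if (!is_count(n)) stopf("n must be a positive integer")
  if (!is.list(pwms) || !length(pwms)) stopf("pwms must be a non-empty list of pwm objects")
  lapply(pwms, function(p) stopifnot(inherits(p, "pwm")))
  m_max <- max(vapply(pwms, function(p) nrow(p$probs), integer(1L)))
  if (!is_count(length, min = m_max)) {
    stopf("sequence length %s must be an integer >= the longest motif (%d)",
          format(length), m_max)
  }
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stopf("prevalence must lie strictly in (0, 1)")
  }
  if (base::length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stopf("background must be a probability vector of length 4")
  }
  if (!is_count(embed_per_positive)) stopf("embed_per_positive must be a positive integer")
  structure(
    list(n = as.integer(n), length = as.integer(length), pwms = pwms,
         prevalence = prevalence, background = as.numeric(background),
         embed_per_positive = as.integer(embed_per_positive),
         revcomp = isTRUE(revcomp), seed = as.integer(seed)),
    class = "sim_config"
  )
}

sample_motif <- function(p) {
  m <- nrow(p$probs)
  idx <- vapply(seq_len(m), function(j) sample.int(4L, 1L, prob = p$probs[j, ]), integer(1L))
  DNA_BASES[idx]
}

revcomp_chars <- function(chars) rev(chartr("ACGT", "TGCA", chars))

#' Simulate a motif-embedded multi-label dataset
#'
#' For every sequence: draw the background from the configured base
#' composition; draw each class label Bernoulli(prevalence); for every
#' positive label write `embed_per_positive` PWM samples of that class at
#' uniform random positions that do not overlap previously placed motifs.
#' Deterministic (bitwise) for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `sequences` (named character vector), `labels`
#'   (a [label_matrix()]) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  C <- length(cfg$pwms)
  class_names <- vapply(cfg$pwms, function(p) p$name, character(1L))
  with_seed(cfg$seed, {
    y <- matrix(stats::rbinom(cfg$n * C, 1L, cfg$prevalence), cfg$n, C)
    seqs <- character(cfg$n)
    for (i in seq_len(cfg$n)) {
      chars <- sample(DNA_BASES, cfg$length, replace = TRUE, prob = cfg$background)
      occupied <- logical(cfg$length)
      for (cl in which(y[i, ] == 1L)) {
        m <- nrow(cfg$pwms[[cl]]$probs)
        for (e in seq_len(cfg$embed_per_positive)) {
          cand <- which(vapply(seq_len(cfg$length - m + 1L), function(s) {
            !any(occupied[s:(s + m - 1L)])
          }, logical(1L)))
          if (!length(cand)) {
            stopf("no room left for a %d-nt motif in sequence %d; increase the sequence length", m, i)
          }
          s <- cand[sample.int(length(cand), 1L)]
          inst <- sample_motif(cfg$pwms[[cl]])
          if (cfg$revcomp && stats::runif(1) < 0.5) inst <- revcomp_chars(inst)
          chars[s:(s + m - 1L)] <- inst
          occupied[s:(s + m - 1L)] <- TRUE
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- sprintf("sim_%0*d", nchar(cfg$n), seq_len(cfg$n))
    list(
      sequences = seqs,
      labels = label_matrix(y, class_names = class_names, ids = names(seqs)),
      config = cfg
    )
  })
}

#' Encode a simulation into a dataset container
#'
#' @param sim result of [simulate_dataset()].
#' @param split_frac training fraction for the attached split (`NULL` for no
#'   split).
#' @param split_seed seed of the split; defaults to the simulation seed.
#' @return a [cac_dataset()].
#' @export
as_cac_dataset <- function(sim, split_frac = 0.92, split_seed = NULL) {
  x <- encode_sequences(unname(sim$sequences))
  split <- if (is.null(split_frac)) NULL else {
    split_train_val(length(sim$sequences), frac = split_frac,
                    seed = split_seed %||% sim$config$seed)
  }
  cac_dataset(x, sim$labels, split = split)
}
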