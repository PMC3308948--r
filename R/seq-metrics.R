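AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.platefit <- new.env(parent = emptyenv())

#' The packaged JTT substitution model
#'
#' Reads the JTT-92 amino-acid exchangeability matrix and equilibrium
#' frequencies shipped with the package (`inst/extdata/jtt_rate_matrix.tsv`,
#' the published accepted-point-mutation counts of Jones, Taylor & Thornton
#' 1992) and assembles the reversible instantaneous rate matrix
#' `Q[i, j] = s[i, j] * pi[j]`, with the diagonal set so rows sum to zero and
#' the whole matrix scaled so that `-sum(pi * diag(Q)) = 1`: one unit of
#' evolutionary distance is one expected substitution per site.
#'
#' @return A list with `Q` (20 x 20 rate matrix), `pi` (equilibrium
#'   frequencies), `s` (raw symmetric exchangeabilities) and the
#'   eigendecomposition used by [jtt_transition_prob()].
#' @export
jtt_model <- function() {
  if (!is.null(.platefit$jtt)) return(.platefit$jtt)
  path <- system.file("extdata", "jtt_rate_matrix.tsv", package = "platefit",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]][-1]
  stopifnot(identical(header, AA20))
  body <- fields[-1]
  freq_row <- vapply(body, function(f) f[1] == "FREQ", logical(1))
  s <- t(vapply(body[!freq_row], function(f) as.numeric(f[-1]),
                numeric(20)))
  dimnames(s) <- list(AA20, AA20)
  stopifnot(isTRUE(all.equal(s, t(s))))
  pi <- as.numeric(body[freq_row][[1]][-1])
  names(pi) <- AA20
  pi <- pi / sum(pi)

  Q <- s * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))          # 1 expected substitution per unit d

  # reversible Q: symmetrise with sqrt(pi) for a stable eigendecomposition
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  .platefit$jtt <- list(
    Q = Q, pi = pi, s = s,
    values = eig$values,
    right = eig$vectors / sq,          # rows scaled:  P = right diag(e) left
    left = t(eig$vectors * sq)
  )
  .platefit$jtt
}

#' JTT transition probability matrix
#'
#' `P(d) = exp(Q d)` for the packaged JTT rate matrix, via the cached
#' eigendecomposition. Rows sum to 1 for any `d >= 0` and `P(0)` is the
#' identity.
#'
#' @param d Evolutionary distance in expected substitutions per site (>= 0).
#' @return A 20 x 20 stochastic matrix over the amino-acid alphabet.
#' @export
jtt_transition_prob <- function(d) {
  stopifnot(is.numeric(d), length(d) == 1, is.finite(d), d >= 0)
  jm <- jtt_model()
  P <- jm$right %*% (exp(jm$values * d) * jm$left)
  dimnames(P) <- list(AA20, AA20)
  # clip the tiny negative entries eigen round-off can leave
  P[P < 0] <- 0
  P / rowSums(P)
}

split_residues <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Uncorrected p-distance between two aligned protein sequences
#'
#' Proportion of differing residues over the aligned columns where both
#' sequences carry a standard amino acid. Columns with a gap (`-` or `.`) in
#' either sequence are excluded (complete deletion over the pair, the
#' default); non-standard letters (`X`, `*`, ...) are likewise excluded.
#'
#' @param seq_a,seq_b Aligned sequences of equal length: single strings or
#'   character vectors of residues.
#' @param ids Length-2 identifier vector for the output row.
#' @return A one-row tibble: `seq_a`, `seq_b`, `sites_used`, `n_diff`,
#'   `p_distance`.
#' @examples
#' p_distance("ACDEF", "ACDEY")
#' @export
p_distance <- function(seq_a, seq_b, ids = c("seq_a", "seq_b")) {
  a <- split_residues(seq_a)
  b <- split_residues(seq_b)
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  use <- a %in% AA20 & b %in% AA20
  if (!any(use)) stop("no gap-free comparable sites in this pair", call. = FALSE)
  n_used <- sum(use)
  n_diff <- sum(a[use] != b[use])
  tibble::tibble(seq_a = ids[1], seq_b = ids[2],
                 sites_used = n_used, n_diff = n_diff,
                 p_distance = n_diff / n_used)
}

#' Maximum-likelihood JTT distance between two aligned protein sequences
#'
#' Estimates the evolutionary distance `d` (expected amino-acid substitutions
#' per site) by maximising the pairwise log-likelihood
#' \deqn{\ell(d) = \sum_{sites} \log\left[\pi(a_s)\, P_{a_s b_s}(d)\right]}
#' under the JTT model with uniform rates across sites, using the packaged
#' rate matrix ([jtt_model()]) and one-dimensional optimisation. Site
#' patterns are collapsed to a 20 x 20 count table first, so cost does not
#' grow with alignment length. A curvature-based standard error
#' (`1/sqrt(-l''(d))`) is reported.
#'
#' Gap handling follows [p_distance()] (complete deletion over the pair).
#' Identical sequences return `jtt_distance = 0` exactly. Saturated pairs
#' whose estimate runs into `max_distance` are flagged `converged = FALSE`.
#'
#' @inheritParams p_distance
#' @param max_distance Upper bound of the search interval (substitutions per
#'   site); estimates at the bound are flagged unconverged.
#' @return A one-row tibble: the [p_distance()] fields plus `jtt_distance`,
#'   `se` and `converged`.
#' @export
jtt_distance <- function(seq_a, seq_b, ids = c("seq_a", "seq_b"),
                         max_distance = 10) {
  a <- split_residues(seq_a)
  b <- split_residues(seq_b)
  pd <- p_distance(a, b, ids = ids)
  use <- a %in% AA20 & b %in% AA20
  counts <- table(factor(a[use], AA20), factor(b[use], AA20))
  counts <- matrix(as.numeric(counts), 20, 20, dimnames = list(AA20, AA20))
  jm <- jtt_model()
  log_pi <- log(jm$pi)

  if (pd$n_diff == 0) {
    return(tibble::tibble(pd, jtt_distance = 0, se = 0, converged = TRUE))
  }

  nz <- which(counts > 0, arr.ind = TRUE)
  n_nz <- counts[nz]
  loglik <- function(d) {
    P <- jtt_transition_prob(d)
    pr <- pmax(P[nz], 1e-300)
    sum(n_nz * (log_pi[nz[, 1]] + log(pr)))
  }
  opt <- stats::optimize(loglik, interval = c(1e-9, max_distance),
                         maximum = TRUE, tol = 1e-9)
  d_hat <- opt$maximum
  converged <- d_hat < max_distance * (1 - 1e-3)
  h <- max(1e-5, d_hat * 1e-3)
  curv <- (loglik(d_hat + h) - 2 * opt$objective + loglik(max(d_hat - h, 1e-9))) / h^2
  se <- if (is.finite(curv) && curv < 0) 1 / sqrt(-curv) else NA_real_
  tibble::tibble(pd, jtt_distance = d_hat, se = se, converged = converged)
}

#' Pairwise protein divergence for an alignment
#'
#' Applies [p_distance()] and [jtt_distance()] to every sequence against a
#' reference (default: the first sequence), or to all pairs.
#'
#' @param sequences Named character vector of aligned sequences, or a path to
#'   an aligned protein FASTA file.
#' @param reference Name of the reference sequence; `NULL` compares all pairs.
#' @param gap_policy `"pairwise"` (default) excludes columns gapped in either
#'   member of each pair; `"complete"` first drops every column gapped in
#'   *any* sequence of the set, so all pairs share one site set.
#' @param ... Passed to [jtt_distance()].
#' @return A tibble with one row per compared pair.
#' @export
protein_divergence <- function(sequences, reference = names(seqs)[1],
                               gap_policy = c("pairwise", "complete"), ...) {
  seqs <- as_sequence_set(sequences, type = "AA")
  gap_policy <- match.arg(gap_policy)
  force(reference)
  if (gap_policy == "complete") {
    mat <- vapply(seqs, function(s) split_residues(s),
                  character(nchar(seqs[[1]])))
    keep <- apply(mat, 1, function(col) all(col %in% AA20))
    if (!any(keep)) stop("no gap-free columns across the set", call. = FALSE)
    seqs <- lapply(seqs, function(s) {
      paste(split_residues(s)[keep], collapse = "")
    })
  }
  if (is.null(reference)) {
    idx <- utils::combn(names(seqs), 2, simplify = FALSE)
  } else {
    if (!reference %in% names(seqs)) {
      stop("reference sequence '", reference, "' not found", call. = FALSE)
    }
    idx <- lapply(setdiff(names(seqs), reference),
                  function(nm) c(reference, nm))
  }
  purrr::list_rbind(lapply(idx, function(pr) {
    jtt_distance(seqs[[pr[1]]], seqs[[pr[2]]], ids = pr, ...)
  }))
}

as_sequence_set <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    set <- if (type == "AA") Biostrings::readAAStringSet(x)
           else Biostrings::readDNAStringSet(x)
    x <- as.character(set)
    names(x) <- sub("\\s.*$", "", names(x))
  }
  if (!is.character(x) || is.null(names(x)) || anyDuplicated(names(x))) {
    stop("sequences must be a FASTA path or a uniquely named character vector",
         call. = FALSE)
  }
  as.list(x)
}

#' Relative adaptiveness of codons from a reference usage table
#'
#' For each amino acid, `w(codon) = count(codon) / count(most used synonymous
#' codon)`, so every amino acid has at least one `w = 1` codon. Codons with a
#' zero count in the reference receive `w_floor` instead of 0 so CAI stays
#' positive (the CodonW convention).
#'
#' @param counts Codon usage of a reference gene set: a named numeric vector
#'   (names = codons) or a data frame with `codon` and `count` columns. Stop
#'   codons are ignored; all sense codons must be present.
#' @param w_floor Relative adaptiveness assigned to zero-count codons
#'   (default 0.01).
#' @return A tibble `codon`, `amino_acid`, `w` sorted by amino acid.
#' @examples
#' # one amino acid with counts 4 and 2 -> w = 1 and 0.5
#' relative_adaptiveness(c(AAA = 4, AAG = 2, TGG = 1))
#' @export
relative_adaptiveness <- function(counts, w_floor = 0.01) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$codon)
  }
  codons <- toupper(gsub("U", "T", names(counts)))
  if (anyDuplicated(codons)) stop("duplicated codons in `counts`", call. = FALSE)
  aa <- genetic_code()[codons]
  if (anyNA(aa)) {
    stop("unknown codon(s): ", paste(codons[is.na(aa)], collapse = ", "),
         call. = FALSE)
  }
  keep <- aa != "*"
  tab <- tibble::tibble(codon = codons[keep], amino_acid = aa[keep],
                        count = as.numeric(counts[keep]))
  out <- dplyr::mutate(dplyr::group_by(tab, .data$amino_acid),
                       max_count = max(.data$count))
  if (any(out$max_count == 0)) {
    bad <- unique(out$amino_acid[out$max_count == 0])
    stop("all-zero reference counts for amino acid(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::ungroup(dplyr::mutate(
    out, w = ifelse(.data$count == 0, w_floor, .data$count / .data$max_count)))
  dplyr::arrange(dplyr::select(out, "codon", "amino_acid", "w"),
                 .data$amino_acid, .data$codon)
}

genetic_code <- function() {
  if (!is.null(.platefit$gc)) return(.platefit$gc)
  .platefit$gc <- Biostrings::GENETIC_CODE
  .platefit$gc
}

#' The packaged E. coli CAI reference weights
#'
#' Relative adaptiveness `w` of each sense codon in the classical
#' *Escherichia coli* high-expression reference gene set (Sharp & Li 1987),
#' as shipped in `inst/extdata/ecoli_cai_weights.tsv`.
#'
#' @return A tibble `codon`, `amino_acid`, `w` (61 sense codons).
#' @export
cai_weights_ecoli <- function() {
  if (!is.null(.platefit$wtab)) return(.platefit$wtab)
  path <- system.file("extdata", "ecoli_cai_weights.tsv", package = "platefit",
                      mustWork = TRUE)
  .platefit$wtab <- readr::read_tsv(path, comment = "#",
                                    show_col_types = FALSE,
                                    progress = FALSE)
  .platefit$wtab
}

#' Codon Adaptation Index of a coding sequence
#'
#' CAI is the geometric mean of the relative adaptiveness `w` of a gene's
#' codons against a high-expression reference set:
#' `CAI = exp(mean(log w))`. Following the CodonW convention, stop codons and
#' the single-codon families Met (ATG) and Trp (TGG) are excluded from the
#' mean, since they carry no codon-bias information. `w` values of zero are
#' floored at `w_floor` so the geometric mean stays positive.
#'
#' @param sequence Coding DNA: a single string, a character vector of
#'   residues, or a path to a (one-sequence-per-gene) FASTA file, in which
#'   case one row per gene is returned.
#' @param w Reference weights as returned by [cai_weights_ecoli()] (default)
#'   or [relative_adaptiveness()].
#' @param id Gene identifier for the output.
#' @param w_floor Floor applied to zero `w` values.
#' @return A tibble with one row per gene: `id`, `n_codons` (codons counted),
#'   `cai`, and a `codon_counts` list-column (named counts over the 64
#'   codons).
#' @examples
#' w <- cai_weights_ecoli()
#' cai("ATGAAACGTTAA", w)   # Met excluded, AAA and CGT counted, stop dropped
#' @export
cai <- function(sequence, w = cai_weights_ecoli(), id = "gene",
                w_floor = 0.01) {
  if (is.character(sequence) && length(sequence) == 1 &&
      file.exists(sequence)) {
    seqs <- as_sequence_set(sequence, type = "DNA")
    return(purrr::list_rbind(purrr::imap(
      seqs, function(s, nm) cai(s, w = w, id = nm, w_floor = w_floor))))
  }
  if (!is.null(names(sequence)) && all(nchar(sequence) > 3)) {
    # a named vector of genes: score each under its own name
    return(purrr::list_rbind(purrr::imap(
      as.list(sequence),
      function(s, nm) cai(s, w = w, id = nm, w_floor = w_floor))))
  }
  s <- split_residues(sequence)
  s <- gsub("U", "T", s)
  s <- s[s != ""]
  if (length(s) == 1 && nchar(s[1]) > 1) s <- strsplit(s, "")[[1]]
  if (length(s) %% 3 != 0) {
    stop("coding sequence length ", length(s), " is not divisible by 3",
         call. = FALSE)
  }
  codons <- vapply(seq_len(length(s) / 3),
                   function(i) paste(s[(3 * i - 2):(3 * i)], collapse = ""),
                   character(1))
  aa <- genetic_code()[codons]
  if (anyNA(aa)) {
    stop("non-standard codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  is_stop <- aa == "*"
  internal <- which(is_stop[-length(is_stop)])
  if (length(internal) > 0) {
    warning("internal stop codon(s) at codon position(s) ",
            paste(internal, collapse = ", "), "; excluded from CAI",
            call. = FALSE)
  }
  counted <- !is_stop & !codons %in% c("ATG", "TGG")
  if (!any(counted)) stop("no codons left to score", call. = FALSE)
  w_map <- stats::setNames(w$w, w$codon)
  wk <- w_map[codons[counted]]
  if (anyNA(wk)) {
    stop("reference weights missing for codon(s): ",
         paste(unique(codons[counted][is.na(wk)]), collapse = ", "),
         call. = FALSE)
  }
  wk[wk <= 0] <- w_floor         # only unobserved (zero-w) codons are floored
  all_codons <- sort(names(genetic_code()))
  cc <- table(factor(codons, levels = all_codons))
  tibble::tibble(id = id, n_codons = sum(counted),
                 cai = exp(mean(log(wk))),
                 codon_counts = list(stats::setNames(as.integer(cc),
                                                     all_codons)))
}
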