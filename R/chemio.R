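#' @importFrom stats rbinom rnorm runif setNames quantile sd cor
#' @importFrom utils head read.csv write.csv tail
NULL

## ---------------------------------------------------------------------------
## SMILES parsing and canonicalization
## ---------------------------------------------------------------------------

#' Canonicalize SMILES strings
#'
#' Converts raw SMILES to canonical, isomeric SMILES (aromatic lowercase,
#' implicit hydrogens) through OpenBabel.  Canonicalization is deterministic
#' and idempotent; every downstream component (tokenizer, graph builder,
#' fingerprints, conformers) consumes canonical SMILES only.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length and order.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(!nzchar(smiles))) stop("empty SMILES string")
  ids <- paste0("m", seq_along(smiles))
  src <- paste(paste(smiles, ids), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  got <- vapply(parts, function(p) p[length(p)], character(1))
  can <- vapply(parts, function(p) p[1L], character(1))
  res <- setNames(rep(NA_character_, length(smiles)), ids)
  res[got] <- can
  if (anyNA(res)) {
    bad <- smiles[is.na(res)]
    stop("unparseable SMILES: ", paste(bad, collapse = ", "))
  }
  unname(res)
}

#' Parse molecules from SMILES
#'
#' Canonicalizes each SMILES and computes the descriptors used throughout the
#' package: heavy-atom count and rotatable-bond count (strict rotor SMARTS,
#' single acyclic non-terminal bonds excluding triple-bond neighbours).
#'
#' @param smiles character vector.
#' @return data.frame with columns `smiles` (canonical), `heavy_atoms`,
#'   `rot_bonds`; class `lm_molecules`.
#' @export
parse_molecules <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  lex <- lapply(can, smiles_atoms)
  heavy <- vapply(lex, nrow, integer(1))
  sdf <- ChemmineR::smiles2sdf(setNames(can, paste0("m", seq_along(can))))
  rot <- as.integer(ChemmineR::smartsSearchOB(
    sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE))
  out <- data.frame(smiles = can, heavy_atoms = heavy, rot_bonds = rot,
                    stringsAsFactors = FALSE)
  class(out) <- c("lm_molecules", "data.frame")
  out
}

# Light SMILES lexer: per-atom element, aromatic flag, formal charge and
# chiral tag, in the order atoms appear in the string (which OpenBabel
# preserves when emitting SDF).  This is an annotator for featurization,
# not a connectivity parser -- bonds come from the toolkit's SDF.
smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elems <- character(0); arom <- logical(0); chg <- integer(0); chir <- integer(0)
  hcnt <- integer(0)  # explicit bracket H count; NA when implicit
  i <- 1L
  two_letter <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      # strip isotope prefix
      body2 <- sub("^[0-9]+", "", body)
      m <- regmatches(body2, regexpr("^[A-Za-z][a-z]?", body2))
      el <- m
      aromatic <- el == tolower(el) && nchar(el) <= 2 && substr(el, 1, 1) %in% letters
      # lowercase second letter of e.g. "Cl" is fine; aromatic only if first lower
      aromatic <- substr(el, 1, 1) %in% c("b", "c", "n", "o", "p", "s")
      elem <- paste0(toupper(substr(el, 1, 1)), substr(el, 2, nchar(el)))
      # H inside brackets is a hydrogen count, not an atom, unless elem == "H"
      rest <- substr(body2, nchar(el) + 1L, nchar(body2))
      charge <- 0L
      if (grepl("\\+", rest)) {
        charge <- sum(gregexpr("\\+", rest)[[1]] > 0)
        num <- regmatches(rest, regexpr("\\+[0-9]+", rest))
        if (length(num)) charge <- as.integer(sub("\\+", "", num))
      } else if (grepl("-", rest)) {
        charge <- -sum(gregexpr("-", rest)[[1]] > 0)
        num <- regmatches(rest, regexpr("-[0-9]+", rest))
        if (length(num)) charge <- -as.integer(sub("-", "", num))
      }
      ctag <- 0L
      if (grepl("@@", rest)) ctag <- 2L else if (grepl("@", rest)) ctag <- 1L
      hh <- 0L
      if (elem != "H" && grepl("H", rest)) {
        hm <- regmatches(rest, regexpr("H[0-9]*", rest))
        hh <- if (nchar(hm) > 1L) as.integer(substr(hm, 2L, nchar(hm))) else 1L
      }
      elems <- c(elems, elem); arom <- c(arom, aromatic)
      chg <- c(chg, charge); chir <- c(chir, ctag); hcnt <- c(hcnt, hh)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "B") && i < n &&
               paste0(ch, chars[i + 1L]) %in% two_letter) {
      elems <- c(elems, paste0(ch, chars[i + 1L])); arom <- c(arom, FALSE)
      chg <- c(chg, 0L); chir <- c(chir, 0L); hcnt <- c(hcnt, NA_integer_)
      i <- i + 2L
    } else if (ch %in% organic) {
      elems <- c(elems, ch); arom <- c(arom, FALSE); chg <- c(chg, 0L); chir <- c(chir, 0L)
      hcnt <- c(hcnt, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elems <- c(elems, toupper(ch)); arom <- c(arom, TRUE); chg <- c(chg, 0L); chir <- c(chir, 0L)
      hcnt <- c(hcnt, NA_integer_)
      i <- i + 1L
    } else {
      i <- i + 1L  # bond symbols, digits, branches, dots
    }
  }
  data.frame(element = elems, aromatic = arom, charge = chg, chiral = chir,
             h_explicit = hcnt, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Vocabulary: byte-pair tokenizer over SMILES characters
## ---------------------------------------------------------------------------

PAD_TOKEN <- "<pad>"
START_TOKEN <- "<s>"
END_TOKEN <- "</s>"

#' Build a byte-pair vocabulary from a SMILES corpus
#'
#' Starts from the single characters occurring in the corpus and greedily
#' merges the most frequent adjacent token pair `merge_budget` times (ties
#' broken lexicographically for determinism).  Special tokens are always
#' present, with the padding token at index 0.
#'
#' @param smiles character vector of (canonical) SMILES.
#' @param merge_budget non-negative integer; number of byte-pair merges.
#' @return object of class `smiles_vocab`: list with `tokens` (token strings
#'   ordered by index, starting at index 0), `index` (named integer map),
#'   `merges` (character vector of merged tokens in rank order).
#' @export
build_vocabulary <- function(smiles, merge_budget = 20L) {
  if (length(smiles) == 0L) stop("empty corpus")
  stopifnot(merge_budget >= 0L)
  seqs <- lapply(smiles, function(s) strsplit(s, "")[[1]])
  base <- sort(unique(unlist(seqs)))
  merges <- character(0)
  for (k in seq_len(merge_budget)) {
    pair_counts <- list()
    tab <- new.env(parent = emptyenv())
    for (sq in seqs) {
      if (length(sq) < 2L) next
      ps <- paste(sq[-length(sq)], sq[-1L], sep = "\r")
      for (p in ps) assign(p, (if (is.null(tab[[p]])) 0L else tab[[p]]) + 1L, envir = tab)
    }
    keys <- ls(tab)
    if (length(keys) == 0L) break
    counts <- vapply(keys, function(k2) tab[[k2]], integer(1))
    best <- sort(keys[counts == max(counts)])[1L]
    halves <- strsplit(best, "\r", fixed = TRUE)[[1]]
    merged <- paste0(halves[1L], halves[2L])
    merges <- c(merges, merged)
    seqs <- lapply(seqs, function(sq) {
      i <- 1L; out <- character(0)
      while (i <= length(sq)) {
        if (i < length(sq) && sq[i] == halves[1L] && sq[i + 1L] == halves[2L]) {
          out <- c(out, merged); i <- i + 2L
        } else { out <- c(out, sq[i]); i <- i + 1L }
      }
      out
    })
  }
  tokens <- c(PAD_TOKEN, START_TOKEN, END_TOKEN, base, merges)
  index <- setNames(seq_along(tokens) - 1L, tokens)
  structure(list(tokens = tokens, index = index, merges = merges),
            class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES byte-pair vocabulary:", length(x$tokens), "tokens,",
      length(x$merges), "merges\n")
  invisible(x)
}

#' Number of tokens in a vocabulary (including specials)
#' @param vocab `smiles_vocab`.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Tokenize SMILES under a vocabulary
#'
#' Greedy longest-match segmentation from left to right; among candidate
#' tokens of the same length the earlier merge rank wins (token order in
#' the vocabulary encodes rank).  Output begins with the start token and
#' ends with the end token; padding never occurs inside a sequence.
#'
#' @param smiles character vector.
#' @param vocab `smiles_vocab`.
#' @return list of integer vectors of token indices (0-based, pad = 0).
#' @export
tokenize_smiles <- function(smiles, vocab) {
  maxlen <- max(nchar(vocab$tokens))
  lapply(smiles, function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    ids <- integer(0)
    i <- 1L
    while (i <= n) {
      hit <- NA_character_
      for (L in seq(min(maxlen, n - i + 1L), 1L)) {
        cand <- paste(chars[i:(i + L - 1L)], collapse = "")
        if (!is.na(vocab$index[cand])) { hit <- cand; break }
      }
      if (is.na(hit)) stop("character not covered by vocabulary: '", chars[i], "'")
      ids <- c(ids, vocab$index[[hit]])
      i <- i + nchar(hit)
    }
    c(vocab$index[[START_TOKEN]], ids, vocab$index[[END_TOKEN]])
  })
}

#' Detokenize a token-index sequence back to a SMILES string
#'
#' @param ids integer vector of token indices (0-based).
#' @param vocab `smiles_vocab`.
#' @return character scalar; special tokens are dropped.
#' @export
detokenize <- function(ids, vocab) {
  toks <- vocab$tokens[ids + 1L]
  toks <- toks[!toks %in% c(PAD_TOKEN, START_TOKEN, END_TOKEN)]
  paste(toks, collapse = "")
}

#' Serialize / load a vocabulary as JSON
#'
#' The vocabulary is persisted with every checkpoint so that decoding is
#' reproducible across sessions.
#' @param vocab `smiles_vocab`.
#' @param path file path.
#' @export
vocab_to_json <- function(vocab, path) {
  jsonlite::write_json(list(index = as.list(vocab$index), merges = vocab$merges),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname vocab_to_json
#' @export
vocab_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- unlist(raw$index)
  tokens <- names(sort(idx))
  structure(list(tokens = tokens, index = setNames(as.integer(sort(idx)), tokens),
                 merges = as.character(raw$merges)),
            class = "smiles_vocab")
}

## ---------------------------------------------------------------------------
## Molecular graph featurization
## ---------------------------------------------------------------------------

ATOM_TYPES <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
ATOM_FEATURE_WIDTH <- 10L + 3L + 4L + 3L + 1L + 1L   # type, hybrid, charge, chiral, ring, aromatic
BOND_FEATURE_WIDTH <- 4L                             # conjugated, ring, stereo none/marked

#' Featurize molecules into atom/bond feature graphs
#'
#' Atom features: element one-hot over C/N/O/S/P/F/Cl/Br/I/other,
#' hybridization one-hot (sp, sp2, sp3), formal charge one-hot
#' (-1, 0, +1, other), chiral tag one-hot (none, @, @@), in-ring flag,
#' aromatic flag.  Bond features: conjugated flag, in-ring flag, stereo
#' one-hot (unmarked, directional-marked).  Hydrogens are implicit; each
#' chemical bond is stored as a pair of directed edges.
#'
#' @param smiles character vector of SMILES.
#' @return list of `mol_graph` objects: `n_atoms`, `n_bonds`,
#'   `atom_features` (n_atoms x 22), `edges` (2*n_bonds x 2, src/dst),
#'   `bond_features` (2*n_bonds x 4), `smiles`.
#' @export
featurize_molecules <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  sdf <- ChemmineR::smiles2sdf(setNames(can, paste0("m", seq_along(can))))
  lapply(seq_along(can), function(i) {
    build_graph(can[i], sdf[[i]])
  })
}

#' @rdname featurize_molecules
#' @export
featurize_molecule <- function(smiles) featurize_molecules(smiles)[[1]]

build_graph <- function(can, sdfmol) {
  lex <- smiles_atoms(can)
  ab <- ChemmineR::atomblock(sdfmol)
  elems_sdf <- gsub("_.*$", "", rownames(ab))
  heavy_idx <- which(!elems_sdf %in% c("H"))
  if (length(heavy_idx) != nrow(lex)) {
    stop("atom-order mismatch between SMILES lexer and SDF for: ", can)
  }
  bb <- ChemmineR::bondblock(sdfmol)
  if (is.null(dim(bb)) || ncol(bb) < 3L) {
    bb <- if (length(bb) >= 3L) matrix(as.numeric(bb[1:3]), 1L, 3L) else matrix(0, 0L, 3L)
  }
  n <- nrow(lex)
  if (nrow(bb) > 0) {
    keep <- bb[, 1] <= n & bb[, 2] <= n  # heavy-heavy bonds only (H appended last)
    bb <- bb[keep, , drop = FALSE]
  }
  m <- nrow(bb)
  src <- if (m) as.integer(bb[, 1]) else integer(0)
  dst <- if (m) as.integer(bb[, 2]) else integer(0)
  order <- if (m) as.integer(bb[, 3]) else integer(0)

  # ring membership: an edge lies on a cycle iff it is not a bridge
  in_ring_bond <- rep(FALSE, m)
  in_ring_atom <- rep(FALSE, n)
  if (m > 0) {
    g <- igraph::graph_from_edgelist(cbind(src, dst), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(m) %in% as.integer(br))
    ring_edges <- which(in_ring_bond)
    in_ring_atom[unique(c(src[ring_edges], dst[ring_edges]))] <- TRUE
  }

  # hybridization: aromatic -> sp2; triple or cumulated double -> sp;
  # any double bond -> sp2; else sp3
  n_double <- n_triple <- rep(0L, n)
  if (m > 0) for (k in seq_len(m)) {
    if (order[k] == 2L) { n_double[src[k]] <- n_double[src[k]] + 1L
                          n_double[dst[k]] <- n_double[dst[k]] + 1L }
    if (order[k] == 3L) { n_triple[src[k]] <- n_triple[src[k]] + 1L
                          n_triple[dst[k]] <- n_triple[dst[k]] + 1L }
  }
  hyb <- ifelse(lex$aromatic, 2L,
         ifelse(n_triple > 0L | n_double >= 2L, 1L,
         ifelse(n_double == 1L, 2L, 3L)))

  af <- matrix(0, n, ATOM_FEATURE_WIDTH)
  ti <- match(lex$element, ATOM_TYPES); ti[is.na(ti)] <- 10L
  af[cbind(seq_len(n), ti)] <- 1
  af[cbind(seq_len(n), 10L + hyb)] <- 1                     # sp=1, sp2=2, sp3=3
  ci <- ifelse(lex$charge == -1L, 1L, ifelse(lex$charge == 0L, 2L,
        ifelse(lex$charge == 1L, 3L, 4L)))
  af[cbind(seq_len(n), 13L + ci)] <- 1
  af[cbind(seq_len(n), 17L + lex$chiral + 1L)] <- 1          # none/@/@@
  af[, 21L] <- as.numeric(in_ring_atom)
  af[, 22L] <- as.numeric(lex$aromatic)

  # bond features
  has_multiple <- (n_double + n_triple) > 0L | lex$aromatic
  has_dir <- grepl("[/\\\\]", can)
  bf1 <- matrix(0, m, BOND_FEATURE_WIDTH)
  if (m > 0) for (k in seq_len(m)) {
    aromatic_bond <- lex$aromatic[src[k]] && lex$aromatic[dst[k]] && in_ring_bond[k]
    conj <- aromatic_bond ||
      (order[k] >= 2L) ||
      (order[k] == 1L && has_multiple[src[k]] && has_multiple[dst[k]])
    stereo_marked <- has_dir && order[k] == 2L && !in_ring_bond[k] &&
      lex$element[src[k]] == "C" && lex$element[dst[k]] == "C"
    bf1[k, 1] <- as.numeric(conj)
    bf1[k, 2] <- as.numeric(in_ring_bond[k])
    bf1[k, 3] <- as.numeric(!stereo_marked)
    bf1[k, 4] <- as.numeric(stereo_marked)
  }
  edges <- rbind(cbind(src, dst), cbind(dst, src))
  bf <- rbind(bf1, bf1)

  structure(list(smiles = can, n_atoms = n, n_bonds = m,
                 atom_features = af, edges = edges, bond_features = bf),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph:", x$smiles, "-", x$n_atoms, "atoms,", x$n_bonds, "bonds\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## File I/O
## ---------------------------------------------------------------------------

#' Read / write SMILES files
#'
#' `.smi` files hold one SMILES per line, optionally followed by a
#' tab-separated identifier.
#' @param path file path.
#' @return data.frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(smiles = vapply(parts, `[`, character(1), 1L),
             id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param smiles character vector of SMILES.
#' @param id optional identifiers.
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SMILES CSV (requires a `smiles` column)
#' @param path file path.
#' @export
read_smiles_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) stop("CSV lacks a 'smiles' column")
  df
}
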