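# Low-level helpers: OpenBabel interop, SMILES tokenization, graph utilities.

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("The 'obabel' executable (OpenBabel) was not found on PATH; ",
         "it is required for structure canonicalization.", call. = FALSE)
  }
  p
}

#' Batch format conversion through OpenBabel
#'
#' Converts a character vector of structure representations with the
#' \command{obabel} command-line tool, keeping input/output alignment through
#' generated title keys. Entries that OpenBabel cannot parse come back as
#' \code{NA} rather than silently shifting the output.
#'
#' @param x character vector of structures (e.g. SMILES or InChI strings).
#' @param from,to OpenBabel format identifiers (e.g. \code{"smi"},
#'   \code{"inchi"}, \code{"can"}, \code{"sdf"}).
#' @param extra additional command-line arguments (e.g. \code{"--neutralize"}).
#' @return character vector the same length as \code{x}; \code{NA} where
#'   conversion failed.
#' @keywords internal
#' @noRd
obConvert <- function(x, from = "smi", to = "can", extra = character()) {
  n <- length(x)
  if (n == 0L) return(character(0))
  ok_in <- !is.na(x) & nzchar(x)
  out <- rep(NA_character_, n)
  if (!any(ok_in)) return(out)
  if (from == "inchi" || to == "inchi") {
    # the InChI reader and writer both discard titles, so alignment is by
    # order, verified by count; on a mismatch, fall back to per-item calls
    out[ok_in] <- .ob_convert_ordered(x[ok_in], from, to, extra)
    return(out)
  }
  keys <- sprintf("hdbk%07d", seq_len(n))
  fin <- tempfile(fileext = paste0(".", from))
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(x[ok_in], keys[ok_in]), fin)
  args <- c(fin, paste0("-i", from), paste0("-o", to), "-O", fout, "-e", extra)
  suppressWarnings(system2(.obabel_path(), args, stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) return(out)
  lines <- readLines(fout, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(out)
  # output lines are "<structure>\t<key>"
  m <- regexpr("hdbk[0-9]{7}", lines)
  key <- ifelse(m > 0, regmatches(lines, m), NA_character_)
  val <- trimws(sub("\\s*hdbk[0-9]{7}\\s*$", "", lines))
  hit <- match(keys, key)
  out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

.ob_convert_ordered <- function(x, from, to, extra = character()) {
  run <- function(values) {
    fin <- tempfile(fileext = paste0(".", from))
    fout <- tempfile(fileext = ".txt")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(values, fin)
    args <- c(fin, paste0("-i", from), paste0("-o", to), "-O", fout, "-e",
              extra)
    suppressWarnings(system2(.obabel_path(), args, stdout = FALSE,
                             stderr = FALSE))
    if (!file.exists(fout)) return(character(0))
    lines <- readLines(fout, warn = FALSE)
    trimws(lines[nzchar(trimws(lines))])
  }
  got <- run(x)
  if (length(got) == length(x)) return(got)
  # some entries failed: resolve one at a time to keep alignment
  vapply(x, function(v) {
    g <- run(v)
    if (length(g) == 1L) g else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# SDF blocks -> canonical SMILES, title-keyed. `blocks` is a character vector,
# each element one complete V2000 block *without* the terminating $$$$ and with
# the title line set to the alignment key already.
obConvertSdfBlocks <- function(blocks) {
  n <- length(blocks)
  if (n == 0L) return(character(0))
  keys <- sprintf("hdbk%07d", seq_len(n))
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(blocks, "\n$$$$"), fin)
  args <- c(fin, "-isdf", "-ocan", "-O", fout, "-e")
  suppressWarnings(system2(.obabel_path(), args, stdout = FALSE, stderr = FALSE))
  out <- rep(NA_character_, n)
  if (!file.exists(fout)) return(out)
  lines <- readLines(fout, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(out)
  m <- regexpr("hdbk[0-9]{7}", lines)
  key <- ifelse(m > 0, regmatches(lines, m), NA_character_)
  val <- trimws(sub("\\s*hdbk[0-9]{7}\\s*$", "", lines))
  hit <- match(keys, key)
  out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

# Elements of the organic subset; anything else counts as a metal for the
# drug-likeness filter (common organic-chemistry convention).
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

#' Tokenize the atoms of a SMILES string
#'
#' Lightweight scanner used for fragment sizing and for the metal/isotope
#' checks of the drug-likeness filter. Handles bracket atoms (with isotope
#' labels and charges), two-letter organic-subset symbols and aromatic
#' lower-case symbols.
#'
#' @param smiles a single SMILES string.
#' @return data.frame with columns \code{element} and \code{isotope}
#'   (logical), one row per atom.
#' @keywords internal
#' @noRd
smilesAtoms <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) {
    return(data.frame(element = character(0), isotope = logical(0)))
  }
  elems <- character(0); iso <- logical(0)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec("^([0-9]*)(se|as|te|si|[A-Z][a-z]?|[bcnops])", body)
      g <- regmatches(body, m)[[1]]
      if (length(g) >= 3L && nzchar(g[3])) {
        sym <- g[3]
        sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
        elems <- c(elems, sym)
        iso <- c(iso, nzchar(g[2]))
      }
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      elems <- c(elems, paste0(ch, chars[i + 1L])); iso <- c(iso, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elems <- c(elems, ch); iso <- c(iso, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elems <- c(elems, toupper(ch)); iso <- c(iso, FALSE); i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(element = elems, isotope = iso, stringsAsFactors = FALSE)
}

# Heavy (non-hydrogen) atom count of a SMILES fragment, by token scan.
smilesHeavyAtoms <- function(smiles) {
  vapply(smiles, function(s) {
    a <- smilesAtoms(s)
    sum(a$element != "H")
  }, integer(1), USE.NAMES = FALSE)
}

# Bridge detection on a small undirected graph given as an edge list
# (two-column integer matrix, 1-based vertex ids). Returns a logical vector,
# one per edge: TRUE when the edge is a bridge (i.e. not part of any ring).
graphBridges <- function(edges, n_vertices) {
  m <- nrow(edges)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n_vertices)
  for (e in seq_len(m)) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  disc <- integer(n_vertices); low <- integer(n_vertices)
  bridge <- logical(m); timer <- 0L
  # iterative DFS to avoid recursion limits
  for (root in seq_len(n_vertices)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, idx = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top$v
      nb <- adj[[v]]
      if (is.null(nb) || top$idx > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          par <- stack[[length(stack)]]
          u <- par$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[top$pe] <- TRUE
        }
        next
      }
      w <- nb[top$idx, 1L]; eid <- nb[top$idx, 2L]
      stack[[length(stack)]]$idx <- top$idx + 1L
      if (eid == top$pe) next
      if (disc[w] == 0L) {
        timer <- timer + 1L; disc[w] <- low[w] <- timer
        stack[[length(stack) + 1L]] <- list(v = w, pe = eid, idx = 1L)
      } else {
        low[v] <- min(low[v], disc[w])
      }
    }
  }
  bridge
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# pIC50 (molar) <-> potency in nM
pic50FromNM <- function(potency_nM) 9 - log10(potency_nM)
nmFromPic50 <- function(pic50) 10^(9 - pic50)

# case-insensitive fixed substring match against a dictionary
matchesAny <- function(text, keywords) {
  if (is.na(text) || !nzchar(text)) return(FALSE)
  lt <- tolower(text)
  any(vapply(keywords, function(k) grepl(k, lt, fixed = TRUE), logical(1)))
}

# structured exclusion log used across pipeline stages
.log_exclusions <- function(df, stage, verbose = FALSE) {
  if (verbose && nrow(df)) {
    tab <- table(df$exclusion_reason)
    for (r in names(tab)) {
      message(sprintf("[%s] excluded %d record(s): %s", stage, tab[[r]], r))
    }
  }
  invisible(df)
}
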