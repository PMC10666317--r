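# shared helpers: tiny deterministic sequences and brute-force oracles

fixturePath <- function(f) {
  p <- system.file("extdata", f, package = "mitokit")
  if (!nzchar(p)) stop("missing fixture: ", f)
  p
}

randomDna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutateFraction <- function(s, frac) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), round(frac * length(ch)))
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

# brute-force SSR enumerator: for every start and unit size, extend a
# perfect periodic run and keep maximal primitive runs meeting the
# thresholds (independent of the package's rle-based scan)
bruteSsrs <- function(s, circular = FALSE,
                      thresholds = c("1" = 10, "2" = 5, "3" = 4,
                                     "4" = 3, "5" = 3, "6" = 3)) {
  L <- nchar(s)
  s2 <- if (circular) paste0(s, s) else s
  ch <- strsplit(s2, "")[[1]]
  primitive <- function(m) {
    u <- nchar(m)
    if (u == 1) return(TRUE)
    for (d in seq_len(u - 1)) if (u %% d == 0 &&
        strrep(substr(m, 1, d), u / d) == m) return(FALSE)
    TRUE
  }
  out <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    i <- 1L
    while (i + u <= length(ch)) {
      # maximal run of period u starting at i (left-maximal check)
      left_ext <- i > 1L && !is.na(ch[i - 1L]) && i - 1L + u <= length(ch) &&
        ch[i - 1L] == ch[i - 1L + u]
      if (!left_ext) {
        j <- i
        while (j + u <= length(ch) && ch[j] == ch[j + u]) j <- j + 1L
        run_len <- (j - i) + u
        copies <- run_len %/% u
        motif <- paste(ch[i:(i + u - 1L)], collapse = "")
        if (copies >= thr && i <= L && !grepl("[^ACGT]", motif) &&
            primitive(motif) &&
            !(circular && i == 1L && ch[L] == ch[u])) {
          copies <- min(copies, L %/% u)
          if (copies >= thr)
            out[[length(out) + 1L]] <- data.frame(
              unit_length = u, copies = copies, start = i,
              end = i + u * copies - 1L)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) return(data.frame(unit_length = integer(0),
                                      copies = integer(0),
                                      start = integer(0),
                                      end = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

# brute-force NG86 pathway difference counts for one codon pair
brutePathwayDiffs <- function(c1, c2) {
  tr <- function(co) {
    aa <- Biostrings::GENETIC_CODE[[co]]
    if (is.null(aa) || aa == "*") "X" else aa
  }
  idx <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(idx)) return(c(sd = 0, nd = 0))
  perms <- if (length(idx) == 1) list(idx) else
    do.call(rbind, combinat_perms(idx))
  if (is.matrix(perms)) perms <- split(perms, row(perms))
  paths <- lapply(perms, function(ord) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    syn <- 0; non <- 0; valid <- TRUE
    for (p in ord) {
      a0 <- tr(paste(cur, collapse = ""))
      cur[p] <- tgt[p]
      a1 <- tr(paste(cur, collapse = ""))
      if (a1 == "X" && !all(cur == tgt)) valid <- FALSE
      if (a0 == a1 && a1 != "X") syn <- syn + 1 else non <- non + 1
    }
    list(syn = syn, non = non, valid = valid)
  })
  ok <- vapply(paths, `[[`, logical(1), "valid")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "syn")),
    nd = mean(vapply(use, `[[`, numeric(1), "non")))
}

# all permutations of a small vector (used by the pathway oracle)
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# hydropathy classification used by the editing oracle (independent table)
oracleHydro <- function(aa) {
  if (aa == "X") return("stop")
  if (aa %in% c("A", "V", "L", "I", "P", "F", "M", "W")) "hydrophobic"
  else "hydrophilic"
}
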