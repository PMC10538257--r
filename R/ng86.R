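GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(GENETIC_CODE_TABLE[codon])

is_stop_codon <- function(codon) translate_codon(codon) == "*"

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each codon position, the fraction of the three possible single-base
#' changes that leave the amino acid unchanged counts towards the synonymous
#' sites of the codon; changes creating a stop codon count as nonsynonymous.
#'
#' @param codon a 3-letter codon string (sense codon).
#' @return `c(S = synonymous sites, N = nonsynonymous sites)`; S + N = 3.
#' @export
ng86_codon_sites <- function(codon) {
  aa <- translate_codon(codon)
  if (aa == "*") stop("site counting undefined for a stop codon")
  nt <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(nt, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (translate_codon(alt) == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# mutation pathway differences between two codons, averaged over orderings;
# paths passing through stop codons are excluded unless every path does, in
# which case all paths are used with stop steps counted nonsynonymous.
ng86_codon_path <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  walk <- function(order) {
    cur <- c1
    sd <- nd <- 0
    through_stop <- FALSE
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (nxt != c2 && is_stop_codon(nxt)) through_stop <- TRUE
      if (translate_codon(cur) == translate_codon(nxt) &&
          !is_stop_codon(nxt) && !is_stop_codon(cur)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    list(sd = sd, nd = nd, through_stop = through_stop)
  }
  paths <- lapply(perms(diff_pos), walk)
  ok <- !vapply(paths, `[[`, logical(1), "through_stop")
  if (any(ok)) paths <- paths[ok]
  c(Sd = mean(vapply(paths, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(paths, `[[`, numeric(1), "nd")))
}

.ng86_cache <- new.env(parent = emptyenv())

ng86_pair_cached <- function(c1, c2) {
  key <- paste0(c1, c2)
  val <- .ng86_cache[[key]]
  if (is.null(val)) {
    val <- ng86_codon_path(c1, c2)
    .ng86_cache[[key]] <- val
  }
  val
}

ng86_sites_cached <- function(codon) {
  key <- paste0("sites_", codon)
  val <- .ng86_cache[[key]]
  if (is.null(val)) {
    val <- ng86_codon_sites(codon)
    .ng86_cache[[key]] <- val
  }
  val
}

# synonymous-site counts for all sense codons, built once
ng86_site_table <- function() {
  tab <- .ng86_cache[["site_table"]]
  if (is.null(tab)) {
    tab <- vapply(SENSE_CODONS, function(cd) ng86_codon_sites(cd)[["S"]],
                  numeric(1))
    .ng86_cache[["site_table"]] <- tab
  }
  tab
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise synonymous/nonsynonymous divergence of two coding sequences
#'
#' Nei-Gojobori (NG86) counting with Jukes-Cantor correction: synonymous and
#' nonsynonymous sites are averaged over the two sequences, differences per
#' codon pair are averaged over mutational pathways, and the proportions are
#' corrected as `d = -3/4 log(1 - 4/3 p)`. A terminal stop codon is trimmed; a
#' premature (internal) stop in either sequence raises an error (callers skip
#' such genes). Codons containing non-ACGT characters are skipped.
#'
#' @param seq1,seq2 equal-length in-frame coding sequences (character).
#' @return list: `S`, `N` (site counts), `Sd`, `Nd` (differences), `ps`, `pn`,
#'   `ds`, `dn` (NA where the JC correction is undefined).
#' @export
ng86_distance <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2))
  cod1 <- split_codons(toupper(seq1))
  cod2 <- split_codons(toupper(seq2))
  n_cod <- length(cod1)
  # trim one terminal stop (shared frame)
  if (n_cod > 0 &&
      (cod1[n_cod] %in% c("TAA", "TAG", "TGA") ||
       cod2[n_cod] %in% c("TAA", "TAG", "TGA"))) {
    cod1 <- cod1[-n_cod]
    cod2 <- cod2[-n_cod]
  }
  clean <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2)
  cod1 <- cod1[clean]
  cod2 <- cod2[clean]
  if (length(cod1) == 0) stop("no usable codons")
  if (any(is_stop_codon(cod1)) || any(is_stop_codon(cod2))) {
    stop("premature stop codon in coding sequence")
  }
  site_tab <- ng86_site_table()
  s1 <- sum(site_tab[cod1])
  s2 <- sum(site_tab[cod2])
  S <- (s1 + s2) / 2
  N <- (3 * length(cod1) * 2 - s1 - s2) / 2
  Sd <- Nd <- 0
  for (i in which(cod1 != cod2)) {
    d <- ng86_pair_cached(cod1[i], cod2[i])
    Sd <- Sd + d[["Sd"]]
    Nd <- Nd + d[["Nd"]]
  }
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ds = jc(ps), dn = jc(pn))
}

#' Per-gene dS between op and cp coding sequences
#'
#' @param cds_op,cds_cp named `DNAStringSet`s (or character vectors) of the
#'   per-gene coding sequences of the two allelic classes, matched by position.
#' @param method `"NG86"` (built-in, default) or `"LWL85"` (delegates to
#'   `seqinr::kaks`, available when seqinr is installed).
#' @return data.frame: gene, ds, dn (NA for genes skipped because of premature
#'   stops or undefined corrections), and attribute `median_ds`.
#' @export
pairwise_ds <- function(cds_op, cds_cp, method = c("NG86", "LWL85")) {
  method <- match.arg(method)
  cds_op <- as.character(cds_op)
  cds_cp <- as.character(cds_cp)
  stopifnot(length(cds_op) == length(cds_cp))
  genes <- names(cds_op)
  if (is.null(genes)) genes <- paste0("gene", seq_along(cds_op))
  ds <- dn <- rep(NA_real_, length(cds_op))
  for (i in seq_along(cds_op)) {
    if (method == "NG86") {
      res <- tryCatch(ng86_distance(cds_op[i], cds_cp[i]),
                      error = function(e) {
                        warning(sprintf("gene %s skipped: %s", genes[i],
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (!is.null(res)) {
        ds[i] <- res$ds
        dn[i] <- res$dn
      }
    } else {
      if (!requireNamespace("seqinr", quietly = TRUE)) {
        stop("LWL85 requires the seqinr package")
      }
      aln <- seqinr::as.alignment(nb = 2, nam = c("op", "cp"),
                                  seq = tolower(c(cds_op[i], cds_cp[i])))
      kk <- tryCatch(seqinr::kaks(aln), error = function(e) NULL)
      if (!is.null(kk)) {
        ds[i] <- as.numeric(kk$ks)[1]
        dn[i] <- as.numeric(kk$ka)[1]
      }
    }
  }
  out <- data.frame(gene = genes, ds = ds, dn = dn, stringsAsFactors = FALSE)
  if (all(is.na(ds))) stop("no usable gene for dS")
  attr(out, "median_ds") <- median(ds, na.rm = TRUE)
  out
}
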