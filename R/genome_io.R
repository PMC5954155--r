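#' Read a genome from FASTA
#'
#' Reads the first record of a FASTA file and validates the alphabet.
#' Coordinates throughout the package are 0-based, half-open, reported on
#' the forward strand.
#'
#' @param fasta_path path to a FASTA file; the first record is used.
#' @param circular is the replicon circular? PAM scanning wraps across the
#'   origin when `TRUE`.
#' @return a `genome_record`: list with `id`, `sequence`, `circular`.
#' @export
read_genome <- function(fasta_path, circular = FALSE) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) < 1L) stop("FASTA has no records: ", fasta_path)
  genome_record(as.character(ss[[1]]), id = names(ss)[1], circular = circular)
}

#' Construct a genome record
#'
#' @param sequence genome sequence, a single string over A/C/G/T.
#' @param id sequence identifier.
#' @param circular logical.
#' @return a `genome_record`.
#' @export
genome_record <- function(sequence, id = "genome", circular = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence is empty")
  if (grepl("[^ACGT]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
    stop("genome contains non-ACGT characters: ", paste(bad, collapse = ", "),
         " (ambiguity codes are not supported)")
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt, %s\n", x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

ESSENTIALITY_LEVELS <- c("essential", "fitness", "neutral")

#' Read gene annotation
#'
#' Accepts either the canonical 7-column TSV
#' (`gene, start, end, strand, essentiality, operon, promoter`) or GFF3 with
#' `essentiality=`/`operon=`/`promoter=` attributes on `gene` features.
#' `promoter` is an optional `start-end` interval (0-based half-open);
#' empty/`.` means none. GFF3 coordinates (1-based closed) are converted.
#'
#' @param path annotation file; `.gff`/`.gff3` extension selects GFF3 parsing.
#' @param genome_length optional; intervals are bounds-checked against it.
#' @return data.frame with columns `gene, start, end, strand, essentiality,
#'   operon, promoter_start, promoter_end`, sorted by `start`.
#' @export
read_annotation <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ann <- read_annotation_gff3(path)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("gene", "start", "end", "strand", "essentiality", "operon", "promoter")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols))
      stop("annotation TSV lacks columns: ", paste(missing_cols, collapse = ", "))
    prom <- parse_promoter_field(tab$promoter)
    ann <- data.frame(gene = as.character(tab$gene),
                      start = as.integer(tab$start), end = as.integer(tab$end),
                      strand = as.character(tab$strand),
                      essentiality = as.character(tab$essentiality),
                      operon = as.character(tab$operon),
                      promoter_start = prom$start, promoter_end = prom$end,
                      stringsAsFactors = FALSE)
  }
  validate_annotation(ann, genome_length)
}

read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(fields, function(f) {
    if (length(f) < 9L) stop("malformed GFF3 line: ", paste(f, collapse = "\t"))
    if (f[3] != "gene") return(NULL)
    attrs <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    kv <- stats::setNames(vapply(attrs, function(a) a[2], character(1)),
                          vapply(attrs, function(a) a[1], character(1)))
    gene <- if (!is.na(kv["ID"])) kv[["ID"]] else kv[["Name"]]
    if (is.na(kv["essentiality"]))
      stop("GFF3 gene ", gene, " lacks an essentiality attribute")
    prom <- if (!is.na(kv["promoter"]) && nzchar(kv[["promoter"]]) && kv[["promoter"]] != ".")
      as.integer(strsplit(kv[["promoter"]], "-", fixed = TRUE)[[1]]) else c(NA_integer_, NA_integer_)
    data.frame(gene = gene,
               start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
               strand = f[7], essentiality = kv[["essentiality"]],
               operon = if (!is.na(kv["operon"])) kv[["operon"]] else gene,
               promoter_start = prom[1], promoter_end = prom[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

parse_promoter_field <- function(x) {
  x <- as.character(x)
  none <- is.na(x) | x %in% c("", ".", "NA")
  start <- rep(NA_integer_, length(x)); end <- rep(NA_integer_, length(x))
  for (i in which(!none)) {
    parts <- as.integer(strsplit(x[i], "-", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts)) stop("bad promoter interval: ", x[i])
    start[i] <- parts[1]; end[i] <- parts[2]
  }
  list(start = start, end = end)
}

validate_annotation <- function(ann, genome_length = NULL) {
  if (anyNA(ann$start) || anyNA(ann$end)) stop("annotation has missing coordinates")
  bad <- ann$start < 0L | ann$start >= ann$end
  if (any(bad)) stop("malformed gene interval for: ", paste(ann$gene[bad], collapse = ", "))
  if (!is.null(genome_length)) {
    over <- ann$end > genome_length
    if (any(over)) stop("gene end beyond genome length for: ",
                        paste(ann$gene[over], collapse = ", "))
  }
  if (!all(ann$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  unknown <- !(ann$essentiality %in% ESSENTIALITY_LEVELS)
  if (any(unknown)) stop("unknown essentiality label '",
                         ann$essentiality[which(unknown)[1]], "' for gene ",
                         ann$gene[which(unknown)[1]],
                         " (expected essential/fitness/neutral)")
  ann[order(ann$start), , drop = FALSE]
}

#' Load genome and annotation together
#'
#' @inheritParams read_genome
#' @param annotation_path annotation TSV or GFF3 (see [read_annotation()]).
#' @return list with `genome` and `annotation`.
#' @export
load_genome <- function(fasta_path, annotation_path, circular = FALSE) {
  genome <- read_genome(fasta_path, circular = circular)
  ann <- read_annotation(annotation_path, genome_length = nchar(genome$sequence))
  list(genome = genome, annotation = ann)
}

#' Scan a genome for NGG PAM sites
#'
#' A forward-strand site at 0-based position `i` has `GG` at `i+1, i+2`; a
#' reverse-strand site at `i` has the NGG on the reverse strand, i.e. `CC`
#' on the forward strand at `i-2, i-1`. `pam_pos` is always the forward
#' coordinate of the first base (the N) of the NGG as read on its own
#' strand. Circular genomes wrap.
#'
#' @param genome a `genome_record`.
#' @return data.frame with columns `pam_pos`, `strand`, sorted by position.
#' @export
scan_pams <- function(genome) {
  ch <- genome_chars(genome)
  L <- length(ch)
  if (genome$circular) {
    at <- function(i) ch[(i %% L) + 1L]
    fwd_idx <- 0:(L - 1L)
    fwd <- fwd_idx[at(fwd_idx + 1L) == "G" & at(fwd_idx + 2L) == "G"]
    rev_ <- fwd_idx[at(fwd_idx - 2L) == "C" & at(fwd_idx - 1L) == "C"]
  } else if (L < 3L) {
    fwd <- integer(0); rev_ <- integer(0)
  } else {
    gg <- ch == "G"
    cc <- ch == "C"
    # forward: 0-based i with G at i+1 and i+2; reverse: CC at i-2, i-1
    fwd <- (0:(L - 3L))[gg[2:(L - 1L)] & gg[3:L]]
    rev_ <- (2:(L - 1L))[cc[1:(L - 2L)] & cc[2:(L - 1L)]]
  }
  out <- rbind(
    data.frame(pam_pos = as.integer(fwd), strand = rep("+", length(fwd)),
               stringsAsFactors = FALSE),
    data.frame(pam_pos = as.integer(rev_), strand = rep("-", length(rev_)),
               stringsAsFactors = FALSE)
  )
  # strand ties broken numerically: character collation is locale-dependent
  out[order(out$pam_pos, out$strand == "-"), , drop = FALSE]
}

#' Extract 20-nt guides at PAM sites
#'
#' The spacer is the 20 nt immediately 5' of the PAM on the protospacer
#' strand; `seed5` is its 5 PAM-proximal bases (the last 5 characters of
#' the spacer). Sites without 20 nt of flank on a linear genome are skipped
#' with a message.
#'
#' @param genome a `genome_record`.
#' @param pam_sites data.frame from [scan_pams()] (or a subset).
#' @param quiet suppress the skip message.
#' @return data.frame with `guide_id, spacer, pam_pos, strand, seed5`.
#' @export
extract_guides <- function(genome, pam_sites, quiet = FALSE) {
  seq <- genome$sequence
  L <- nchar(seq)
  pos <- pam_sites$pam_pos
  strand <- pam_sites$strand
  if (genome$circular) {
    ok <- rep(TRUE, length(pos))
  } else {
    ok <- ifelse(strand == "+", pos - 20L >= 0L, pos + 21L <= L)
  }
  n_skip <- sum(!ok)
  if (n_skip > 0L && !quiet)
    message("extract_guides: skipped ", n_skip, " site(s) with <20 nt of flank")
  pos <- pos[ok]; strand <- strand[ok]
  if (length(pos) == 0L)
    return(data.frame(guide_id = character(0), spacer = character(0),
                      pam_pos = integer(0), strand = character(0),
                      seed5 = character(0), stringsAsFactors = FALSE))
  spacer <- character(length(pos))
  is_p <- strand == "+"
  # non-wrapping sites vectorized; wrap-around (circular only) handled per site
  wrap_p <- is_p & (pos - 20L < 0L)
  wrap_m <- !is_p & (pos + 21L > L)
  plain_p <- is_p & !wrap_p
  plain_m <- !is_p & !wrap_m
  if (any(plain_p))
    spacer[plain_p] <- substring(seq, pos[plain_p] - 19L, pos[plain_p])
  if (any(plain_m))
    spacer[plain_m] <- revcomp(substring(seq, pos[plain_m] + 2L, pos[plain_m] + 21L))
  for (i in which(wrap_p | wrap_m)) {
    if (is_p[i]) {
      spacer[i] <- genome_substr(genome, pos[i] - 20L, pos[i])
    } else {
      spacer[i] <- revcomp(genome_substr(genome, pos[i] + 1L, pos[i] + 21L))
    }
  }
  data.frame(
    guide_id = sprintf("g%07d_%s", pos, ifelse(strand == "+", "p", "m")),
    spacer = spacer, pam_pos = as.integer(pos), strand = strand,
    seed5 = substr(spacer, 16L, 20L), stringsAsFactors = FALSE
  )
}

#' Annotate guides with gene context
#'
#' Orientation convention: `coding` means the protospacer (+PAM) lies on
#' the gene's sense (non-template) strand — the orientation in which dCas9
#' blocks transcription elongation; `template` is the opposite;
#' `promoter` when the PAM falls inside an annotated promoter interval
#' outside any gene body; `intergenic` otherwise. Gene assignment uses the
#' PAM position; overlapping genes resolve to the first by coordinate.
#' Distances are measured from the PAM-proximal spacer base.
#' Guides whose spacer occurs at more than one extracted site are flagged
#' `multi_mapping`.
#'
#' @param guides data.frame from [extract_guides()].
#' @param annotation data.frame from [read_annotation()].
#' @return `guides` with columns `target_gene, orientation, dist_from_start,
#'   dist_from_end, rel_pos, multi_mapping` added.
#' @export
annotate_guides <- function(guides, annotation) {
  n <- nrow(guides)
  target_gene <- rep(NA_character_, n)
  orientation <- rep("intergenic", n)
  dist_from_start <- rep(NA_integer_, n)
  dist_from_end <- rep(NA_integer_, n)
  rel_pos <- rep(NA_real_, n)

  # guide location: the PAM-proximal spacer base
  loc <- ifelse(guides$strand == "+", guides$pam_pos - 1L, guides$pam_pos + 1L)

  for (i in seq_len(n)) {
    p <- guides$pam_pos[i]
    hit <- which(annotation$start <= p & p < annotation$end)
    if (length(hit) > 0L) {
      g <- annotation[hit[1L], ]
      target_gene[i] <- g$gene
      orientation[i] <- if (guides$strand[i] == g$strand) "coding" else "template"
      len <- g$end - g$start
      if (g$strand == "+") {
        dist_from_start[i] <- loc[i] - g$start
        dist_from_end[i] <- (g$end - 1L) - loc[i]
      } else {
        dist_from_start[i] <- (g$end - 1L) - loc[i]
        dist_from_end[i] <- loc[i] - g$start
      }
      rel_pos[i] <- if (len > 1L) dist_from_start[i] / (len - 1L) else 0
      rel_pos[i] <- min(max(rel_pos[i], 0), 1)
    } else {
      prom <- which(!is.na(annotation$promoter_start) &
                      annotation$promoter_start <= p & p < annotation$promoter_end)
      if (length(prom) > 0L) {
        target_gene[i] <- annotation$gene[prom[1L]]
        orientation[i] <- "promoter"
      }
    }
  }
  guides$target_gene <- target_gene
  guides$orientation <- orientation
  guides$dist_from_start <- dist_from_start
  guides$dist_from_end <- dist_from_end
  guides$rel_pos <- rel_pos
  guides$multi_mapping <- guides$spacer %in% guides$spacer[duplicated(guides$spacer)]
  guides
}

#' Extract the target-context window around each guide
#'
#' Returns, in protospacer orientation, a window of `up` nt of upstream
#' context, the 20-nt spacer, the 3-nt PAM and `down` nt of downstream
#' context (default 20 + 20 + 3 + 17 = 60 nt, spacer at positions 21-40).
#' Guides whose window leaves a linear genome get `NA`.
#'
#' @param genome a `genome_record`.
#' @param guides guide table.
#' @param up,down context widths in nt.
#' @return character vector of windows (or `NA`), one per guide.
#' @export
guide_context_window <- function(genome, guides, up = 20L, down = 17L) {
  L <- nchar(genome$sequence)
  out <- rep(NA_character_, nrow(guides))
  for (i in seq_len(nrow(guides))) {
    p <- guides$pam_pos[i]
    if (guides$strand[i] == "+") {
      s0 <- p - 20L - up; e0 <- p + 3L + down
      if (genome$circular || (s0 >= 0L && e0 <= L))
        out[i] <- genome_substr(genome, s0, e0)
    } else {
      s0 <- p - 2L - down; e0 <- p + 21L + up
      if (genome$circular || (s0 >= 0L && e0 <= L))
        out[i] <- revcomp(genome_substr(genome, s0, e0))
    }
  }
  out
}

#' Write / read a guide table as TSV
#'
#' @param guides guide data.frame.
#' @param path file path.
#' @export
write_guides_tsv <- function(guides, path) {
  utils::write.table(guides, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_guides_tsv
#' @export
read_guides_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
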