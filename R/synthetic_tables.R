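# Generators for alignments with planted conservation structure and
# annotation tables with planted pathway enrichment.

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# run code with a private RNG state so generators are seed-deterministic
# without disturbing the caller's random stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Generate an alignment with planted column conservation
#'
#' Every column draws residues i.i.d. from a column-specific mixture: one
#' dominant residue with probability \code{p_in} (columns inside the
#' designated motif region) or \code{p_out} (all other columns), the
#' remaining mass spread uniformly over the other 19 amino acids. Higher
#' dominant-residue probability means higher conservation.
#'
#' @param n_seqs number of sequences (>= 2).
#' @param L alignment length (columns).
#' @param rlm_columns integer vector of column indices inside the motif.
#' @param p_in,p_out dominant-residue probabilities inside / outside.
#' @param seed integer seed; same inputs give identical output.
#' @return character matrix (n_seqs x L) with rownames seq1..seqN and
#'   attribute \code{rlm_columns}.
#' @export
makeMSA <- function(n_seqs = 30L, L = 200L, rlm_columns = 1:60,
                    p_in = 0.9, p_out = 0.3, seed = 1L) {
  stopifnot(n_seqs >= 2L, L >= 1L, p_in >= 0, p_in <= 1, p_out >= 0,
            p_out <= 1)
  .with_seed(seed, {
    m <- matrix("", n_seqs, L)
    dom <- sample(.AA, L, replace = TRUE)
    for (j in seq_len(L)) {
      p <- if (j %in% rlm_columns) p_in else p_out
      probs <- rep((1 - p) / 19, 20)
      probs[match(dom[j], .AA)] <- p
      m[, j] <- sample(.AA, n_seqs, replace = TRUE, prob = probs)
    }
    rownames(m) <- paste0("seq", seq_len(n_seqs))
    attr(m, "rlm_columns") <- rlm_columns
    m
  })
}

#' Write an alignment matrix as aligned FASTA
#'
#' @param msa character matrix (rows = sequences).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMSA <- function(msa, path) {
  lines <- character(0)
  for (i in seq_len(nrow(msa)))
    lines <- c(lines, paste0(">", rownames(msa)[i]),
               paste(msa[i, ], collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Generate annotation tables with planted pathway enrichment
#'
#' Builds an EC list spread over pathway classes, pathway membership tables
#' and a motif (RLM) flag per EC. Within each class the probability that an
#' EC is flagged is \code{rlm_fraction} times the class's fold (capped at 1),
#' planting over-representation that downstream enrichment statistics should
#' recover. Ground-truth folds are attached for recovery tests.
#'
#' @param n_ec number of EC entries.
#' @param n_pathways number of pathways spread uniformly over classes.
#' @param n_classes number of pathway classes in the major group.
#' @param rlm_fraction baseline probability that an EC is motif-bearing.
#' @param enriched_classes named numeric vector of per-class folds (names
#'   are class indices as "class3"), default none.
#' @param frac_dashed fraction of additional dashed EC entries appended.
#' @param seed integer seed.
#' @return list with \code{ec} (data.frame ec/class/rlm), \code{pathways}
#'   (pathway/class/major_group), \code{membership} (pathway/ec) and
#'   \code{folds} (ground truth per class).
#' @export
makeAnnotationTables <- function(n_ec = 2000L, n_pathways = 40L,
                                 n_classes = 8L, rlm_fraction = 0.3,
                                 enriched_classes = numeric(),
                                 frac_dashed = 0, seed = 1L) {
  stopifnot(rlm_fraction >= 0, rlm_fraction <= 1,
            all(enriched_classes > 0))
  .with_seed(seed, {
    classes <- paste0("class", seq_len(n_classes))
    folds <- stats::setNames(rep(1, n_classes), classes)
    if (length(enriched_classes))
      folds[names(enriched_classes)] <- enriched_classes
    ec <- sprintf("%d.%d.%d.%d", sample(1:7, n_ec, TRUE),
                  sample(1:20, n_ec, TRUE), sample(1:20, n_ec, TRUE),
                  seq_len(n_ec))
    cls <- sample(classes, n_ec, replace = TRUE)
    p_rlm <- pmin(1, rlm_fraction * folds[cls])
    rlm <- stats::runif(n_ec) < p_rlm
    ecdf_ <- data.frame(ec = ec, class = cls, rlm = rlm,
                        stringsAsFactors = FALSE)
    if (frac_dashed > 0) {
      nd <- ceiling(frac_dashed * n_ec)
      dashed <- sprintf("%d.%d.%d.-", sample(1:7, nd, TRUE),
                        sample(1:20, nd, TRUE), sample(1:20, nd, TRUE))
      ecdf_ <- rbind(ecdf_, data.frame(ec = dashed,
                                       class = sample(classes, nd, TRUE),
                                       rlm = stats::runif(nd) < rlm_fraction,
                                       stringsAsFactors = FALSE))
    }
    pw <- data.frame(pathway = sprintf("map%05d", seq_len(n_pathways)),
                     class = classes[(seq_len(n_pathways) - 1L) %%
                                       n_classes + 1L],
                     major_group = "global metabolism",
                     stringsAsFactors = FALSE)
    memb <- do.call(rbind, lapply(seq_len(nrow(pw)), function(i) {
      pool <- ecdf_$ec[ecdf_$class == pw$class[i] & !grepl("-", ecdf_$ec,
                                                           fixed = TRUE)]
      if (length(pool) == 0L) return(NULL)
      take <- sample(pool, max(1L, ceiling(length(pool) / 2)))
      data.frame(pathway = pw$pathway[i], ec = take, stringsAsFactors = FALSE)
    }))
    list(ec = ecdf_, pathways = pw, membership = memb, folds = folds)
  })
}

#' Per-class enrichment counts from an annotation bundle
#'
#' Collapses a generated (or loaded) annotation bundle to the per-class 2x2
#' counts that \code{\link{enrichmentTable}} consumes: non-redundant ECs per
#' class (dashed ECs removed first) split by motif status.
#'
#' @param tables list as from \code{\link{makeAnnotationTables}} (components
#'   \code{ec}, \code{pathways}, \code{membership}).
#' @return list with \code{class_counts} (class/class_rlm/class_all),
#'   \code{group_rlm}, \code{group_all}.
#' @export
pathwayClassCounts <- function(tables) {
  keep <- filterDashed(tables$ec$ec)
  ec <- tables$ec[tables$ec$ec %in% keep, , drop = FALSE]
  mapped <- unique(tables$membership$ec)
  ec <- ec[ec$ec %in% mapped, , drop = FALSE]
  cls_of_pathway <- stats::setNames(tables$pathways$class,
                                    tables$pathways$pathway)
  memb <- tables$membership[tables$membership$ec %in% ec$ec, , drop = FALSE]
  memb$class <- cls_of_pathway[memb$pathway]
  rlm_of <- stats::setNames(ec$rlm, ec$ec)
  per_class <- lapply(split(memb$ec, memb$class), unique)
  class_counts <- data.frame(
    class = names(per_class),
    class_rlm = vapply(per_class, function(e) sum(rlm_of[e]), integer(1)),
    class_all = vapply(per_class, length, integer(1)),
    stringsAsFactors = FALSE)
  rownames(class_counts) <- NULL
  list(class_counts = class_counts,
       group_rlm = sum(rlm_of[unique(memb$ec)]),
       group_all = length(unique(memb$ec)))
}

#' Write an annotation bundle as TSV files
#'
#' @param tables list as from \code{\link{makeAnnotationTables}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeAnnotationTables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("ec", "pathways", "membership"))
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
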