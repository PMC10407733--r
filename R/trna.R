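#' Construct a Sprinzl-numbered tRNA sequence
#'
#' Bases are indexed by standard Sprinzl positions (1-76, gaps
#' allowed). The acceptor stem is modeled explicitly as the pair map
#' (1,72) ... (7,66); each present pair must be Watson-Crick
#' complementary (G:U wobble pairs are tolerated with a warning).
#'
#' @param name sequence name.
#' @param bases named character vector of bases (`A`, `C`, `G`, `U`;
#'   `T` is converted); names are Sprinzl positions. The discriminator
#'   (73) and the anticodon (34-36) must be present.
#' @param var_loop_len variable-loop length; defaults to the number of
#'   present positions in 44-48. Supply explicitly for class II tRNAs
#'   with an extended variable arm.
#' @return object of class `trna_seq`.
#' @export
trna_seq <- function(name, bases, var_loop_len = NULL) {
  pos <- suppressWarnings(as.integer(names(bases)))
  if (any(is.na(pos))) stop("base names must be integer Sprinzl positions")
  if (any(pos < 1 | pos > 76)) stop("Sprinzl positions must lie in 1..76")
  if (anyDuplicated(pos)) stop("duplicate Sprinzl positions")
  b <- toupper(as.character(bases))
  b[b == "T"] <- "U"
  if (!all(b %in% c("A", "C", "G", "U")))
    stop("bases must be A, C, G or U")
  names(b) <- pos
  if (!"73" %in% names(b)) stop("discriminator position 73 is required")
  if (!all(c("34", "35", "36") %in% names(b)))
    stop("anticodon positions 34-36 are required")
  wobble <- character(0)
  for (p in seq_len(7)) {
    p5 <- as.character(p)
    p3 <- as.character(73 - p)
    if (p5 %in% names(b) && p3 %in% names(b)) {
      pair <- paste0(b[[p5]], b[[p3]])
      if (pair %in% c("GU", "UG")) {
        wobble <- c(wobble, sprintf("%s%s:%s%s", b[[p5]], p5, b[[p3]], p3))
      } else if (!pair %in% c("AU", "UA", "GC", "CG")) {
        stop(sprintf("acceptor pair %s:%s (%s) is not complementary",
                     p5, p3, pair))
      }
    }
  }
  if (length(wobble))
    warning("G:U wobble in acceptor stem: ", paste(wobble, collapse = ", "))
  if (is.null(var_loop_len))
    var_loop_len <- sum(names(b) %in% as.character(44:48))
  structure(list(name = name, bases = b, var_loop_len = var_loop_len,
                 wobble_pairs = wobble),
            class = "trna_seq")
}

#' @export
print.trna_seq <- function(x, ...) {
  cat(sprintf("<trna_seq> %s: %d positions, anticodon %s, discriminator %s%s\n",
              x$name, length(x$bases),
              paste(x$bases[c("34", "35", "36")], collapse = ""),
              x$bases[["73"]],
              if (x$var_loop_len >= 10) ", extended variable loop" else ""))
  invisible(x)
}

#' Read a tRNA from a Sprinzl positions table
#'
#' @param path TSV with columns `sprinzl_position` and `base`; `#`
#'   lines are comments.
#' @param name sequence name; defaults to the file name.
#' @param var_loop_len optional explicit variable-loop length.
#' @return a [trna_seq()].
#' @export
read_trna <- function(path, name = NULL, var_loop_len = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sprinzl_position", "base") %in% names(df)))
    stop("need columns sprinzl_position and base")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  trna_seq(name, stats::setNames(df$base, df$sprinzl_position),
           var_loop_len = var_loop_len)
}

#' The shipped tRNA-pSer model
#'
#' Synthetic Sprinzl-position reconstruction of the orthogonal
#' phosphoserine suppressor tRNA: the characterized features (acceptor
#' pairs G1:C72 and C2:G71, discriminator U73, CUA anticodon, short
#' variable loop) are as described for the real molecule; the remaining
#' positions are generic cloverleaf filler.
#'
#' @return a [trna_seq()].
#' @export
trna_pser <- function() {
  read_trna(system.file("extdata", "trna_pser_positions.tsv",
                        package = "otstox"),
            name = "tRNA-pSer")
}

#' Write tRNA sequences to FASTA
#'
#' Bases are concatenated in Sprinzl-position order.
#'
#' @param seqs a [trna_seq()] or list of them.
#' @param path output file.
#' @export
write_trna_fasta <- function(seqs, path) {
  if (inherits(seqs, "trna_seq")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    ord <- order(as.integer(names(s$bases)))
    c(paste0(">", s$name), paste(s$bases[ord], collapse = ""))
  }))
  writeLines(lines, path)
}

#' Construct an identity element
#'
#' A base, base-pair or structural feature by which an aminoacyl-tRNA
#' synthetase recognizes its tRNA.
#'
#' @param kind `"base"`, `"base_pair"` or `"structural"`.
#' @param pos5 Sprinzl position (the 5' position for pairs).
#' @param pos3 3' Sprinzl position (pairs only).
#' @param required required base (`"U"`) or pair (`"G:C"`).
#' @param feature structural feature name; currently
#'   `"extended_variable_loop"`.
#' @param threshold numeric threshold for structural predicates
#'   (minimum variable-loop length).
#' @param essential logical; an essential element must stay matched for
#'   cognate recognition, and an essential structural element vetoes
#'   host flagging when unmet.
#' @return object of class `identity_element`.
#' @export
identity_element <- function(kind = c("base", "base_pair", "structural"),
                             pos5 = NA, pos3 = NA, required = NA,
                             feature = NA, threshold = NA,
                             essential = FALSE) {
  kind <- match.arg(kind)
  if (kind == "base") {
    if (is.na(pos5) || is.na(required)) stop("base elements need pos5 and required")
    if (!required %in% c("A", "C", "G", "U")) stop("required base must be A/C/G/U")
  } else if (kind == "base_pair") {
    if (is.na(pos5) || is.na(pos3) || is.na(required))
      stop("base_pair elements need pos5, pos3 and required")
    if (!grepl("^[ACGU]:[ACGU]$", required))
      stop("required pair must look like 'G:C'")
  } else {
    if (is.na(feature)) stop("structural elements need a feature name")
  }
  label <- switch(kind,
    base = sprintf("%s%d", required, as.integer(pos5)),
    base_pair = {
      parts <- strsplit(required, ":", fixed = TRUE)[[1]]
      sprintf("%s%d:%s%d", parts[1], as.integer(pos5), parts[2],
              as.integer(pos3))
    },
    structural = feature)
  structure(list(kind = kind, pos5 = pos5, pos3 = pos3, required = required,
                 feature = feature, threshold = threshold,
                 essential = essential, label = label),
            class = "identity_element")
}

#' Construct a recognition profile
#'
#' @param aars synthetase name.
#' @param elements list of [identity_element()] objects, non-empty.
#' @param flag_threshold minimum matched elements for
#'   [screen_host_recognition()] to flag this synthetase.
#' @return object of class `recognition_profile`.
#' @export
recognition_profile <- function(aars, elements, flag_threshold = 3) {
  if (!length(elements)) stop("a profile needs at least one element")
  if (!all(vapply(elements, inherits, logical(1), "identity_element")))
    stop("elements must be identity_element objects")
  structure(list(aars = aars, elements = elements,
                 flag_threshold = flag_threshold),
            class = "recognition_profile")
}

#' Read an identity-element catalog
#'
#' TSV columns: `aars`, `kind`, `pos5`, `pos3`, `required`,
#' `structural_feature`, `threshold`, `essential`, `flag_threshold`
#' (and optionally `source`). Returns one profile per synthetase.
#'
#' @param path TSV file path; `#` lines are comments.
#' @return named list of [recognition_profile()] objects.
#' @export
read_identity_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("aars", "kind", "pos5", "pos3", "required", "structural_feature",
           "threshold", "essential", "flag_threshold")
  if (!all(req %in% names(df)))
    stop("catalog needs columns: ", paste(req, collapse = ", "))
  profiles <- lapply(split(df, df$aars), function(g) {
    els <- lapply(seq_len(nrow(g)), function(i) {
      identity_element(kind = g$kind[i], pos5 = g$pos5[i], pos3 = g$pos3[i],
                       required = g$required[i],
                       feature = g$structural_feature[i],
                       threshold = g$threshold[i],
                       essential = isTRUE(g$essential[i]))
    })
    recognition_profile(g$aars[1], els, flag_threshold = g$flag_threshold[1])
  })
  profiles
}

#' The shipped identity-element catalog
#'
#' Encodes the characterized recognition elements relevant to the
#' phosphoserine orthogonal pair in E. coli: GlyRS and ThrRS recognize
#' the acceptor pairs G1:C72 and C2:G71 plus the discriminator U73;
#' SerRS recognition requires the extended variable loop (an essential
#' structural element) alongside literature-supplemented acceptor
#' elements; pSerRS essentially requires G1:C72 and U73. The `source`
#' column distinguishes directly characterized entries from
#' literature-supplemented ones; the TSV is editable and extensible.
#'
#' @return named list of [recognition_profile()] objects.
#' @export
identity_catalog <- function() {
  read_identity_catalog(system.file("extdata", "identity_elements.tsv",
                                    package = "otstox"))
}

#' Does a tRNA match one identity element?
#'
#' @param seq a [trna_seq()].
#' @param element an [identity_element()].
#' @return logical.
#' @export
element_matches <- function(seq, element) {
  stopifnot(inherits(seq, "trna_seq"), inherits(element, "identity_element"))
  b <- seq$bases
  if (element$kind == "base") {
    p <- as.character(as.integer(element$pos5))
    if (!p %in% names(b)) stop("position absent from sequence: ", p)
    return(b[[p]] == element$required)
  }
  if (element$kind == "base_pair") {
    p5 <- as.character(as.integer(element$pos5))
    p3 <- as.character(as.integer(element$pos3))
    if (!p5 %in% names(b)) stop("position absent from sequence: ", p5)
    if (!p3 %in% names(b)) stop("position absent from sequence: ", p3)
    parts <- strsplit(element$required, ":", fixed = TRUE)[[1]]
    return(b[[p5]] == parts[1] && b[[p3]] == parts[2])
  }
  if (element$feature == "extended_variable_loop") {
    thr <- if (is.na(element$threshold)) 10 else element$threshold
    return(seq$var_loop_len >= thr)
  }
  stop("unknown structural feature: ", element$feature)
}

#' Elements of a profile matched by a tRNA
#'
#' @param seq a [trna_seq()].
#' @param profile a [recognition_profile()].
#' @return character vector of matched element labels (subset of the
#'   profile's element labels; deterministic, order-independent).
#' @export
overlap_elements <- function(seq, profile) {
  stopifnot(inherits(profile, "recognition_profile"))
  hit <- vapply(profile$elements, function(e) element_matches(seq, e),
                logical(1))
  vapply(profile$elements[hit], `[[`, character(1), "label")
}

#' Screen a tRNA against host synthetase recognition profiles
#'
#' A synthetase is flagged as a misrecognition risk when its matched
#' element count reaches its `flag_threshold` and no essential
#' structural element is unmet (the structural veto).
#'
#' @param seq a [trna_seq()].
#' @param profiles list of [recognition_profile()] objects.
#' @return data frame sorted by matched count (decreasing) then name:
#'   `aars`, `n_matched`, `n_elements`, `matched` (comma-joined
#'   labels), `structural_ok`, `flagged`.
#' @export
screen_host_recognition <- function(seq, profiles) {
  if (!length(profiles)) stop("need at least one profile")
  rows <- lapply(profiles, function(pr) {
    matched <- overlap_elements(seq, pr)
    veto <- vapply(pr$elements, function(e) {
      e$kind == "structural" && isTRUE(e$essential) && !element_matches(seq, e)
    }, logical(1))
    structural_ok <- !any(veto)
    data.frame(aars = pr$aars, n_matched = length(matched),
               n_elements = length(pr$elements),
               matched = paste(matched, collapse = ","),
               structural_ok = structural_ok,
               flagged = structural_ok & length(matched) >= pr$flag_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_matched, out$aars), , drop = FALSE]
}

#' Flip an acceptor-stem base pair
#'
#' Swaps the bases at the two positions of an acceptor-stem pair (e.g.
#' C2:G71 becomes G2:C71), preserving complementarity and every other
#' position. Applying the same flip twice restores the original
#' sequence.
#'
#' @param seq a [trna_seq()].
#' @param pair integer length-2 vector, an acceptor pair such as
#'   `c(2, 71)`.
#' @return the mutated [trna_seq()], renamed with a `.flip<p5>:<p3>`
#'   suffix toggled on the name.
#' @export
flip_base_pair <- function(seq, pair) {
  stopifnot(inherits(seq, "trna_seq"))
  p5 <- as.integer(pair[1])
  p3 <- as.integer(pair[2])
  acceptor <- cbind(1:7, 72:66)
  if (!any(acceptor[, 1] == p5 & acceptor[, 2] == p3))
    stop(sprintf("(%d,%d) is not an acceptor-stem pair", p5, p3))
  b <- seq$bases
  k5 <- as.character(p5)
  k3 <- as.character(p3)
  if (!k5 %in% names(b) || !k3 %in% names(b))
    stop("pair positions absent from the sequence")
  tmp <- b[[k5]]
  b[[k5]] <- b[[k3]]
  b[[k3]] <- tmp
  suffix <- sprintf(".flip%d:%d", p5, p3)
  new_name <- if (endsWith(seq$name, suffix)) {
    substr(seq$name, 1, nchar(seq$name) - nchar(suffix))
  } else {
    paste0(seq$name, suffix)
  }
  trna_seq(new_name, b, var_loop_len = seq$var_loop_len)
}

#' Propose orthogonalizing mutations
#'
#' Enumerates single acceptor-stem pair flips and single discriminator
#' substitutions; keeps candidates that (a) leave every cognate element
#' matched and (b) strictly reduce the total matched-element count
#' summed over the host profiles. Candidates are ranked by that
#' reduction.
#'
#' @param seq a [trna_seq()].
#' @param cognate the orthogonal synthetase's [recognition_profile()].
#' @param host_profiles list of host [recognition_profile()] objects.
#' @return data frame (possibly empty): `mutation`, `type`,
#'   `host_matches_before`, `host_matches_after`, `reduction`.
#' @export
propose_orthogonalizing_mutations <- function(seq, cognate, host_profiles) {
  stopifnot(inherits(cognate, "recognition_profile"))
  total_host <- function(s)
    sum(vapply(host_profiles, function(pr) length(overlap_elements(s, pr)),
               numeric(1)))
  cognate_intact <- function(s)
    all(vapply(cognate$elements, function(e) element_matches(s, e), logical(1)))
  before <- total_host(seq)
  cands <- list()
  for (p in 1:7) {
    pr <- c(p, 73 - p)
    if (!all(as.character(pr) %in% names(seq$bases))) next
    mut <- flip_base_pair(seq, pr)
    cands[[length(cands) + 1]] <- list(
      label = sprintf("flip(%d,%d) %s%d:%s%d->%s%d:%s%d", pr[1], pr[2],
                      seq$bases[[as.character(pr[1])]], pr[1],
                      seq$bases[[as.character(pr[2])]], pr[2],
                      mut$bases[[as.character(pr[1])]], pr[1],
                      mut$bases[[as.character(pr[2])]], pr[2]),
      type = "pair_flip", seq = mut)
  }
  for (nb in setdiff(c("A", "C", "G", "U"), seq$bases[["73"]])) {
    b <- seq$bases
    b[["73"]] <- nb
    mut <- trna_seq(paste0(seq$name, ".d73", nb), b,
                    var_loop_len = seq$var_loop_len)
    cands[[length(cands) + 1]] <- list(
      label = sprintf("discriminator %s73->%s73", seq$bases[["73"]], nb),
      type = "discriminator", seq = mut)
  }
  rows <- lapply(cands, function(cd) {
    if (!cognate_intact(cd$seq)) return(NULL)
    after <- total_host(cd$seq)
    if (after >= before) return(NULL)
    data.frame(mutation = cd$label, type = cd$type,
               host_matches_before = before, host_matches_after = after,
               reduction = before - after, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(mutation = character(0), type = character(0),
                      host_matches_before = numeric(0),
                      host_matches_after = numeric(0),
                      reduction = numeric(0)))
  out[order(-out$reduction, out$mutation), , drop = FALSE]
}
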