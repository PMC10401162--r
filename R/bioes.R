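ENTITY_KINDS <- c("motif", "domain", "region")

#' An amino-acid sequence with entity span annotations
#'
#' Couples a one-letter-code protein sequence with motif/domain/region
#' spans. Coordinates are 1-based and inclusive, following UniProt feature
#' conventions (a feature covering residues 346-375 has `start = 346`,
#' `end = 375`). Spans of the same kind must not overlap; spans of
#' different kinds may (they live on separate annotation tracks).
#'
#' @param sequence Character scalar of one-letter amino-acid codes.
#' @param entities Data frame with columns `start`, `end`, `category`,
#'   `kind` (each kind one of `"motif"`, `"domain"`, `"region"`); may have
#'   zero rows.
#' @param sequence_id Optional identifier.
#' @return An object of class `annotated_sequence`.
#' @examples
#' annotated_sequence("MSSLSAK",
#'   data.frame(start = 2, end = 6, category = "Motif1", kind = "motif"))
#' @export
annotated_sequence <- function(sequence, entities = NULL, sequence_id = "seq1") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  L <- nchar(sequence)
  if (is.null(entities))
    entities <- data.frame(start = integer(0), end = integer(0),
                           category = character(0), kind = character(0),
                           stringsAsFactors = FALSE)
  need <- c("start", "end", "category", "kind")
  if (!all(need %in% names(entities)))
    stop("entities must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  entities <- entities[need]
  entities$start <- as.integer(entities$start)
  entities$end <- as.integer(entities$end)
  entities$category <- as.character(entities$category)
  entities$kind <- as.character(entities$kind)
  if (nrow(entities)) {
    if (!all(entities$kind %in% ENTITY_KINDS))
      stop("entity kind must be one of ", paste(ENTITY_KINDS, collapse = ", "),
           call. = FALSE)
    bad <- entities$start < 1L | entities$end > L |
      entities$start > entities$end
    if (any(bad))
      stop(sprintf(
        "span out of bounds: [%d, %d] does not fit a sequence of length %d",
        entities$start[bad][1L], entities$end[bad][1L], L), call. = FALSE)
    for (kd in unique(entities$kind)) {
      e <- entities[entities$kind == kd, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
        stop("overlapping '", kd, "' spans are not allowed", call. = FALSE)
    }
  }
  structure(list(sequence_id = sequence_id, sequence = sequence,
                 entities = entities),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("<annotated_sequence> '%s': %d residues, %d spans\n",
              x$sequence_id, nchar(x$sequence), nrow(x$entities)))
  invisible(x)
}

#' Merge rare categories into "Other"
#'
#' Annotation category frequencies are heavily long-tailed; categories
#' observed fewer than `min_count` times are merged into a single sentinel
#' category `"Other"` so the tail does not destabilize downstream
#' classification. The mapping is retained for encode-time lookup.
#'
#' @param counts Named numeric vector (or named list) of nonnegative
#'   occurrence counts per category.
#' @param min_count Threshold; categories with `count < min_count` map to
#'   `"Other"`. `min_count = 0` keeps every category.
#' @return An object of class `category_vocabulary`: retained `categories`
#'   (always including `"Other"`), the original `counts`, `min_count`, and
#'   the full `mapping` (named character vector, original -> resolved).
#' @examples
#' merge_long_tail(c(A = 100, B = 1, C = 1), min_count = 5)
#' @export
merge_long_tail <- function(counts, min_count) {
  counts <- unlist(counts)
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(nzchar(names(counts))))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  stopifnot(is.numeric(min_count), length(min_count) == 1L, min_count >= 0)
  keep <- counts >= min_count
  mapping <- ifelse(keep, names(counts), "Other")
  names(mapping) <- names(counts)
  structure(list(
    categories = unique(c(names(counts)[keep], "Other")),
    counts = counts, min_count = min_count, mapping = mapping),
    class = "category_vocabulary")
}

#' @export
print.category_vocabulary <- function(x, ...) {
  merged <- sum(x$mapping == "Other" & names(x$mapping) != "Other")
  cat(sprintf(
    "<category_vocabulary> %d retained categories (min_count = %g), %d merged into 'Other'\n",
    length(x$categories), x$min_count, merged))
  invisible(x)
}

resolve_category <- function(category, vocab) {
  if (is.null(vocab)) return(category)
  stopifnot(inherits(vocab, "category_vocabulary"))
  out <- unname(vocab$mapping[category])
  out[is.na(out)] <- "Other"   # unseen category -> sentinel
  out
}

encode_track <- function(L, spans) {
  tags <- rep("O", L)
  for (r in seq_len(nrow(spans))) {
    s <- spans$start[r]; e <- spans$end[r]; cat <- spans$category[r]
    if (s == e) tags[s] <- paste0("S-", cat)
    else {
      tags[s] <- paste0("B-", cat)
      if (e > s + 1L) tags[(s + 1L):(e - 1L)] <- paste0("I-", cat)
      tags[e] <- paste0("E-", cat)
    }
  }
  tags
}

#' Encode annotations as BIOES tags
#'
#' Each residue receives a tag: `O` outside any entity, `S-<Category>` for a
#' single-residue entity, and `B-`/`I-`/`E-<Category>` for the begin,
#' inside and end residues of a multi-residue entity. By default each
#' annotation kind (motif, domain, region) is encoded on its own track;
#' `combine_kinds = TRUE` produces one track and therefore requires that no
#' spans overlap across kinds.
#'
#' @param seq An [annotated_sequence()].
#' @param vocab Optional [merge_long_tail()] vocabulary; categories are
#'   resolved through it (unknown categories become `"Other"`).
#' @param combine_kinds Encode all kinds on a single track (default FALSE).
#' @return An object of class `bioes_tags`: `tracks`, a named list of
#'   character vectors (one tag per residue), plus the sequence and its id.
#' @examples
#' a <- annotated_sequence("MSSLSAK",
#'   data.frame(start = 2, end = 6, category = "Motif1", kind = "motif"))
#' encode_bioes(a)$tracks$motif
#' @export
encode_bioes <- function(seq, vocab = NULL, combine_kinds = FALSE) {
  stopifnot(inherits(seq, "annotated_sequence"))
  L <- nchar(seq$sequence)
  ents <- seq$entities
  ents$category <- resolve_category(ents$category, vocab)
  if (combine_kinds) {
    e <- ents[order(ents$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("combine_kinds = TRUE requires spans not to overlap across kinds",
           call. = FALSE)
    tracks <- list(combined = encode_track(L, e))
  } else {
    tracks <- lapply(ENTITY_KINDS, function(kd)
      encode_track(L, ents[ents$kind == kd, , drop = FALSE]))
    names(tracks) <- ENTITY_KINDS
  }
  structure(list(sequence_id = seq$sequence_id, sequence = seq$sequence,
                 tracks = tracks),
            class = "bioes_tags")
}

#' @export
print.bioes_tags <- function(x, ...) {
  cat(sprintf("<bioes_tags> '%s': %d residues, tracks: %s\n", x$sequence_id,
              nchar(x$sequence), paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}

#' Decode one BIOES tag track back to spans
#'
#' Inverse of [encode_bioes()] for a single track. The tag sequence must
#' satisfy the BIOES grammar: every non-`O` run of one category is either a
#' single `S` or exactly `B (I)* E` with one category throughout; any
#' violation (dangling `B`, `I`/`E` without `B`, category switch mid-entity)
#' raises a decode error naming the offending position.
#'
#' @param tags Character vector of tags (`"O"` or `"<P>-<Category>"`,
#'   `P` one of B, I, E, S).
#' @return Data frame with columns `start`, `end`, `category` (1-based
#'   inclusive spans, ordered by start).
#' @examples
#' decode_bioes(c("O", "B-x", "E-x"))
#' @export
decode_bioes <- function(tags) {
  stopifnot(is.character(tags), length(tags) >= 1L)
  starts <- integer(0); ends <- integer(0); cats <- character(0)
  open_start <- NA_integer_; open_cat <- NA_character_
  bad <- function(i, why)
    stop(sprintf("decode error at position %d: %s", i, why), call. = FALSE)
  for (i in seq_along(tags)) {
    tg <- tags[[i]]
    if (tg == "O") {
      if (!is.na(open_start)) bad(i, "entity opened by B was never closed by E")
      next
    }
    if (!grepl("^[BIES]-.+$", tg)) bad(i, paste0("malformed tag '", tg, "'"))
    pre <- substr(tg, 1L, 1L)
    cat <- substring(tg, 3L)
    if (pre == "S") {
      if (!is.na(open_start)) bad(i, "S inside an open entity")
      starts <- c(starts, i); ends <- c(ends, i); cats <- c(cats, cat)
    } else if (pre == "B") {
      if (!is.na(open_start)) bad(i, "B inside an open entity")
      open_start <- i; open_cat <- cat
    } else if (pre == "I") {
      if (is.na(open_start)) bad(i, "I without a preceding B")
      if (!identical(cat, open_cat)) bad(i, "category switch inside an entity")
    } else { # E
      if (is.na(open_start)) bad(i, "E without a preceding B")
      if (!identical(cat, open_cat)) bad(i, "category switch inside an entity")
      starts <- c(starts, open_start); ends <- c(ends, i)
      cats <- c(cats, cat)
      open_start <- NA_integer_; open_cat <- NA_character_
    }
  }
  if (!is.na(open_start))
    bad(length(tags), "entity opened by B was never closed by E")
  out <- data.frame(start = starts, end = ends, category = cats,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Read span annotations from a TSV file
#'
#' Expects columns `sequence_id`, `sequence`, `kind`, `category`, `start`,
#' `end`; one row per span, rows of one sequence repeating its sequence
#' string. Rows with an empty `kind` declare an unannotated sequence.
#'
#' @param path TSV file path.
#' @return A list of [annotated_sequence()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "sequence", "kind", "category", "start", "end")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, factor(df$sequence_id, levels = unique(df$sequence_id))),
         function(g) {
    id <- g$sequence_id[1L]
    sq <- unique(g$sequence)
    if (length(sq) != 1L)
      stop("conflicting sequences for id ", id, call. = FALSE)
    g <- g[nzchar(g$kind) & !is.na(g$kind), , drop = FALSE]
    annotated_sequence(sq, g[c("start", "end", "category", "kind")],
                       sequence_id = id)
  })
}

#' Write BIOES tags as a TSV table
#'
#' One row per residue and track, columns `sequence_id`, `position`,
#' `residue`, `kind`, `tag`.
#'
#' @param tag_list A `bioes_tags` object or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bioes_tags <- function(tag_list, path) {
  if (inherits(tag_list, "bioes_tags")) tag_list <- list(tag_list)
  rows <- do.call(rbind, lapply(tag_list, function(bt) {
    L <- nchar(bt$sequence)
    res <- strsplit(bt$sequence, "")[[1L]]
    do.call(rbind, lapply(names(bt$tracks), function(kd)
      data.frame(sequence_id = bt$sequence_id, position = seq_len(L),
                 residue = res, kind = kd, tag = bt$tracks[[kd]],
                 stringsAsFactors = FALSE)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
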