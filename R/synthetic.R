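#' Specification for a synthetic multi-book corpus
#'
#' Controls the shape of the generated corpus: a books -> chapters ->
#' knowledge-points hierarchy in which every knowledge point owns a distinct
#' vocabulary cluster (so an ideal embedder separates points), states one
#' planted subject-predicate-object fact, and may cross-link to a point in
#' another chapter (sharing tokens across chapters, the minimal instance of
#' cross-chapter reasoning).
#'
#' @param n_books,chapters_per_book,points_per_chapter tree shape (all >= 1).
#' @param words_per_point approximate words per knowledge point (default 250,
#'   the midpoint of the 200-300-word chunking band, so each point maps to
#'   one chunk).
#' @param vocabulary_size filler-token pool size per cluster.
#' @param cross_link_rate fraction of points referencing a point in another
#'   chapter, in `[0, 1]`.
#' @param seed integer seed; generation is fully deterministic under it.
#' @return a `corpus_spec`.
#' @export
corpus_spec <- function(n_books = 2L, chapters_per_book = 3L,
                        points_per_chapter = 3L, words_per_point = 250L,
                        vocabulary_size = 40L, cross_link_rate = 0.3,
                        seed = 1L) {
  stopifnot(n_books >= 1L, chapters_per_book >= 1L, points_per_chapter >= 1L,
            words_per_point >= 1L, vocabulary_size >= 1L,
            cross_link_rate >= 0, cross_link_rate <= 1)
  structure(list(n_books = as.integer(n_books),
                 chapters_per_book = as.integer(chapters_per_book),
                 points_per_chapter = as.integer(points_per_chapter),
                 words_per_point = as.integer(words_per_point),
                 vocabulary_size = as.integer(vocabulary_size),
                 cross_link_rate = cross_link_rate,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

predicate_surface <- function(pred) gsub("_", " ", pred, fixed = TRUE)

cluster_tokens <- function(k, size) sprintf("w%d_%d", k, seq_len(size))

#' Generate a synthetic corpus with planted facts
#'
#' Deterministic under the spec seed. Each knowledge point's paragraph opens
#' with its planted fact sentence ("subject predicate object"), continues
#' with filler sentences drawn from the point's own vocabulary cluster, and —
#' for cross-linked points — closes with a `belongs to` sentence naming the
#' partner point's subject plus a few partner-cluster tokens. Point headings
#' are the subject entities, so the default triple extractor yields the
#' planted triples verbatim.
#'
#' @param spec a `corpus_spec`.
#' @return a `synthetic_corpus`: `documents` (raw heading-dialect texts, one
#'   per book), `points` (per-point records: `key`, `book`, `chapter`,
#'   `subject`, `predicate`, `object`, `heading_path`, `partner` key or
#'   `NA`), and the `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- default_vocabulary()
  points <- list(); k <- 0L
  for (b in seq_len(spec$n_books)) for (cc in seq_len(spec$chapters_per_book))
    for (p in seq_len(spec$points_per_chapter)) {
      k <- k + 1L
      subject <- sprintf("entity_b%dc%dp%d", b, cc, p)
      points[[k]] <- list(
        key = k, book = b, chapter = cc, point = p, subject = subject,
        predicate = vocab[(k - 1L) %% length(vocab) + 1L],
        object = sprintf("finding_b%dc%dp%d", b, cc, p),
        heading_path = c(sprintf("Book %d", b),
                         sprintf("Chapter %d.%d", b, cc), subject),
        partner = NA_integer_)
    }
  n_pts <- length(points)
  chapter_of <- vapply(points, function(pt) paste(pt$book, pt$chapter),
                       character(1))

  with_seed(spec$seed, {
    # plant cross-chapter links
    for (i in seq_len(n_pts)) {
      others <- which(chapter_of != chapter_of[i])
      if (length(others) && stats::runif(1) < spec$cross_link_rate)
        points[[i]]$partner <- others[sample.int(length(others), 1L)]
    }
    paragraphs <- character(n_pts)
    for (i in seq_len(n_pts)) {
      pt <- points[[i]]
      sentences <- sprintf("%s %s %s.", pt$subject,
                           predicate_surface(pt$predicate), pt$object)
      pool <- cluster_tokens(pt$key, spec$vocabulary_size)
      n_filler <- max(0L, ceiling((spec$words_per_point - 4L) / 10))
      for (j in seq_len(n_filler)) {
        words <- pool[sample.int(length(pool), 10L, replace = TRUE)]
        sentences <- c(sentences, paste0(paste(words, collapse = " "), "."))
      }
      if (!is.na(pt$partner)) {
        partner <- points[[pt$partner]]
        sentences <- c(sentences,
                       sprintf("%s belongs to %s.", pt$subject, partner$subject),
                       paste0(paste(cluster_tokens(partner$key, 5L),
                                    collapse = " "), "."))
      }
      paragraphs[i] <- paste(sentences, collapse = " ")
    }
  })

  documents <- character(spec$n_books)
  for (b in seq_len(spec$n_books)) {
    lines <- c(sprintf("# Book %d", b), "")
    for (cc in seq_len(spec$chapters_per_book)) {
      lines <- c(lines, sprintf("## Chapter %d.%d", b, cc), "")
      for (i in seq_len(n_pts)) {
        pt <- points[[i]]
        if (pt$book == b && pt$chapter == cc)
          lines <- c(lines, sprintf("### %s", pt$subject), "",
                     paragraphs[i], "")
      }
    }
    documents[b] <- paste(lines, collapse = "\n")
  }
  structure(list(documents = as.list(documents), points = points, spec = spec),
            class = "synthetic_corpus")
}

#' Oracle embedder for a synthetic corpus
#'
#' One-hot-by-cluster embedder: every token belonging to a knowledge point's
#' vocabulary cluster (its filler tokens, subject and object entities) maps
#' to that point's dimension; all other tokens are ignored. Under this
#' embedder, distinct points have orthogonal embeddings, the idealized limit
#' of a perfect semantic model.
#'
#' @param corpus a `synthetic_corpus`.
#' @return a batch embedder `function(texts) -> matrix`.
#' @export
oracle_embedder <- function(corpus) {
  dim <- length(corpus$points)
  entity_cluster <- new.env(parent = emptyenv())
  for (pt in corpus$points) {
    entity_cluster[[tolower(pt$subject)]] <- pt$key
    entity_cluster[[tolower(pt$object)]] <- pt$key
  }
  function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      for (t in tokenize(texts[[i]])) {
        m <- regmatches(t, regexec("^w([0-9]+)_", t))[[1]]
        kk <- if (length(m)) as.integer(m[2]) else entity_cluster[[t]]
        if (!is.null(kk) && !is.na(kk) && kk >= 1L && kk <= dim)
          out[i, kk] <- out[i, kk] + 1
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
}

#' Units planted for a knowledge point
#'
#' Looks up the leaf node labelled with the point's subject and returns its
#' attached unit ids and chunk ids — the ground-truth targets for retrieval
#' metrics.
#'
#' @param kb a `knowledge_base` built from the corpus documents.
#' @param point a point record from `corpus$points`.
#' @return list with `unit_ids` and `chunk_ids`.
#' @export
point_units <- function(kb, point) {
  leaf <- find_node_by_path(kb, point$heading_path)
  if (is.null(leaf))
    stop_tosrr(sprintf("planted point '%s' not found in knowledge base",
                       point$subject), "tosrr_consistency_error")
  uids <- kb$nodes[[leaf]]$unit_ids
  list(unit_ids = uids,
       chunk_ids = unique(vapply(uids, function(u) kb$units[[u]]$chunk_id,
                                 character(1))))
}

#' Generate a multiple-choice bank with planted truth
#'
#' Factual items (fraction `factual_fraction`, rounded half-up) ask for the
#' object of one planted triple; case-analysis items require combining a
#' cross-linked pair: the stem names one point's subject and asks what the
#' partner topic's fact states, so answering needs both points. Distractors
#' are objects of sibling points. Deterministic under `seed`.
#'
#' @param corpus a `synthetic_corpus`.
#' @param n_items number of items.
#' @param factual_fraction fraction of factual items (default 0.7, matching
#'   the 70/30 factual / case-analysis exam mix).
#' @param seed integer seed.
#' @return list with `bank` (list of `mcq_item`) and `truth` (per item:
#'   `item_id`, `category`, `point_keys`, `answer_text`, `entities`).
#' @export
generate_mcq <- function(corpus, n_items, factual_fraction = 0.7, seed = 1L) {
  points <- corpus$points
  n_pts <- length(points)
  stopifnot(n_pts >= 2L)
  n_factual <- as.integer(round_half_up(n_items * factual_fraction, 0))
  n_case <- n_items - n_factual
  linked <- which(!vapply(points, function(pt) is.na(pt$partner), logical(1)))
  if (n_case > 0L && !length(linked))
    stop_tosrr("case-analysis items need cross-linked points (cross_link_rate > 0)",
               "tosrr_input_error")
  all_objects <- vapply(points, function(pt) pt$object, character(1))

  with_seed(seed, {
    bank <- list(); truth <- list()
    make_options <- function(answer, exclude_keys) {
      distract <- setdiff(all_objects, c(answer, all_objects[exclude_keys]))
      n_d <- min(4L, length(distract))
      opts <- c(answer, distract[sample.int(length(distract), n_d)])
      opts <- opts[sample.int(length(opts))]
      names(opts) <- LETTERS[seq_along(opts)]
      opts
    }
    fact_keys <- if (n_factual > 0L)
      sample.int(n_pts, n_factual, replace = n_factual > n_pts)
    else integer(0)
    for (i in seq_len(n_factual)) {
      pt <- points[[fact_keys[i]]]
      opts <- make_options(pt$object, pt$key)
      item_id <- sprintf("fact_%03d", i)
      bank[[length(bank) + 1L]] <- mcq_item(
        item_id,
        sprintf("Which of the following does %s %s?", pt$subject,
                predicate_surface(pt$predicate)),
        opts, names(opts)[match(pt$object, opts)], "factual")
      truth[[length(truth) + 1L]] <- list(
        item_id = item_id, category = "factual", point_keys = pt$key,
        answer_text = pt$object,
        entities = c(pt$subject, pt$object))
    }
    case_keys <- if (n_case > 0L)
      linked[sample.int(length(linked), n_case, replace = n_case > length(linked))]
    else integer(0)
    for (i in seq_len(n_case)) {
      pt <- points[[case_keys[i]]]
      partner <- points[[pt$partner]]
      opts <- make_options(partner$object, c(pt$key, partner$key))
      item_id <- sprintf("case_%03d", i)
      bank[[length(bank) + 1L]] <- mcq_item(
        item_id,
        sprintf("%s belongs to a broader topic; which finding does that topic %s?",
                pt$subject, predicate_surface(partner$predicate)),
        opts, names(opts)[match(partner$object, opts)], "case_analysis")
      truth[[length(truth) + 1L]] <- list(
        item_id = item_id, category = "case_analysis",
        point_keys = c(pt$key, partner$key), answer_text = partner$object,
        entities = c(pt$subject, partner$subject, partner$object))
    }
    list(bank = bank, truth = truth)
  })
}

#' Generate a synthetic rater matrix with controllable concordance
#'
#' Each rater's scores are a convex mixture of a latent item quality (shared
#' by all raters) and rater-specific uniform noise; the `concordance`
#' parameter monotonically controls the expected Kendall's W, from
#' independent rankings (`0`, expected W near `1/n_raters`) to identical
#' rankings (`1`, W = 1).
#'
#' @param n_raters number of raters (default 10).
#' @param n_items number of rated items.
#' @param concordance mixing weight in `[0, 1]`.
#' @param seed integer seed.
#' @return numeric matrix, raters in rows.
#' @export
generate_rater_matrix <- function(n_raters = 10L, n_items, concordance,
                                  seed = 1L) {
  stopifnot(concordance >= 0, concordance <= 1, n_items >= 2L, n_raters >= 1L)
  with_seed(seed, {
    quality <- stats::runif(n_items)
    t(vapply(seq_len(n_raters), function(r)
      concordance * quality + (1 - concordance) * stats::runif(n_items),
      numeric(n_items)))
  })
}
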