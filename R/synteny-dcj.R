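#' Signed gene order
#'
#' A genome abstracted to ordered, oriented markers on one or more
#' chromosomes. Markers are integers 1..N (a marker alphabet shared between
#' the two genomes being compared); sign encodes strand.
#'
#' @param chromosomes List of integer vectors of signed marker ids.
#' @param shapes Character vector, `"circular"` or `"linear"` per chromosome.
#' @param marker_names Optional character vector naming markers 1..N.
#' @return An object of class `signed_gene_order`.
#' @export
signed_gene_order <- function(chromosomes, shapes = rep("circular",
                                                        length(chromosomes)),
                              marker_names = NULL) {
  stopifnot(length(chromosomes) == length(shapes),
            all(shapes %in% c("circular", "linear")))
  ids <- abs(unlist(chromosomes))
  if (anyDuplicated(ids))
    stop("marker id(s) appear more than once: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(ids == 0)) stop("marker ids must be non-zero")
  structure(list(chromosomes = lapply(chromosomes, as.integer),
                 shapes = shapes, marker_names = marker_names),
            class = "signed_gene_order")
}

#' @export
print.signed_gene_order <- function(x, ...) {
  for (i in seq_along(x$chromosomes)) {
    m <- x$chromosomes[[i]]
    lab <- if (!is.null(x$marker_names))
      paste0(ifelse(m > 0, "+", "-"), x$marker_names[abs(m)])
    else sprintf("%+d", m)
    cat(sprintf("<signed_gene_order> chr%d (%s): %s\n", i, x$shapes[i],
                paste(lab, collapse = " ")))
  }
  invisible(x)
}

#' Reduce two annotated genomes to shared single-copy marker orders
#'
#' Markers are the harmonized gene names present exactly once in each
#' genome; order follows the genomic coordinate around each circle and sign
#' follows strand. Both outputs cover the identical marker alphabet, so they
#' can be fed to [dcj_distance()]. This gene-order reduction stands in for
#' alignment-derived collinear blocks: it captures the same rearrangement
#' signal whenever gene content is largely shared.
#'
#' @param a,b [genome_record()] objects.
#' @param synonyms A [synonym_table()] used to harmonize names first.
#' @param kinds Feature kinds treated as gene markers.
#' @return List of two [signed_gene_order()] objects named `a` and `b`.
#' @export
shared_marker_orders <- function(a, b, synonyms = synonym_table(),
                                 kinds = c("CDS", "gene")) {
  grab <- function(rec) {
    feats <- Filter(function(f) f$kind %in% kinds & !is.na(f$name),
                    rec$features)
    if ("CDS" %in% vapply(feats, `[[`, character(1), "kind"))
      feats <- Filter(function(f) f$kind == "CDS", feats)
    data.frame(
      name = vapply(feats, `[[`, character(1), "name"),
      start = vapply(feats, function(f) f$location[[1]]$start, integer(1)),
      strand = vapply(feats, `[[`, character(1), "strand"),
      stringsAsFactors = FALSE)
  }
  fa <- grab(a); fb <- grab(b)
  map <- harmonize_map(list(a = fa$name, b = fb$name), synonyms)
  canon_map <- function(nm) ifelse(nm %in% names(map), map[nm], nm)
  fa$canon <- canon_map(fa$name)
  fb$canon <- canon_map(fb$name)
  single_a <- names(which(table(fa$canon) == 1L))
  single_b <- names(which(table(fb$canon) == 1L))
  shared <- intersect(single_a, single_b)
  if (length(shared) < 3L)
    stop("insufficient data: only ", length(shared),
         " shared single-copy markers")
  shared <- sort(shared)
  build <- function(fd, rec) {
    fd <- fd[fd$canon %in% shared, , drop = FALSE]
    fd <- fd[order(fd$start), , drop = FALSE]
    ids <- match(fd$canon, shared)
    signed_gene_order(list(ifelse(fd$strand == "+", ids, -ids)),
                      shapes = rec$topology, marker_names = shared)
  }
  list(a = build(fa, a), b = build(fb, b))
}

# --- adjacency graph -------------------------------------------------------
# Extremities: marker m has tail 2m-1 and head 2m. Reading a chromosome
# left to right, +m is traversed tail->head, -m head->tail. An adjacency
# joins the right extremity of one marker to the left extremity of the next;
# circular chromosomes close the loop, linear ones contribute telomeres.

.extremities <- function(m) {
  # returns c(left, right) extremity ids for signed marker m
  if (m > 0) c(2L * m - 1L, 2L * m) else c(2L * abs(m), 2L * abs(m) - 1L)
}

# adjacency list of a signed_gene_order: matrix with 2 columns (0 = telomere
# partner never appears; telomeres returned separately)
.genome_adjacencies <- function(g) {
  adj <- matrix(integer(), ncol = 2)
  telo <- integer()
  for (ci in seq_along(g$chromosomes)) {
    chr <- g$chromosomes[[ci]]
    ext <- t(vapply(chr, .extremities, integer(2)))
    k <- length(chr)
    if (k == 0L) next
    if (g$shapes[ci] == "circular") {
      nxt <- c(seq_len(k)[-1], 1L)
      adj <- rbind(adj, cbind(ext[, 2], ext[nxt, 1]))
    } else {
      if (k > 1L) adj <- rbind(adj, cbind(ext[-k, 2], ext[-1, 1]))
      telo <- c(telo, ext[1, 1], ext[k, 2])
    }
  }
  list(adj = adj, telo = telo)
}

#' Adjacency graph of two signed gene orders
#'
#' The multigraph on marker extremities whose edges are the adjacencies of
#' the two genomes. Its components are cycles and paths; with `N` markers,
#' `C` cycles and `I` odd-length paths, the DCJ distance is
#' `N - (C + I/2)`.
#'
#' @param a,b [signed_gene_order()] objects over the same marker set.
#' @return A list with `N`, `C`, `I`, and `components`.
#' @export
adjacency_graph <- function(a, b) {
  ma <- sort(abs(unlist(a$chromosomes)))
  mb <- sort(abs(unlist(b$chromosomes)))
  if (!identical(ma, mb)) {
    d <- c(setdiff(ma, mb), setdiff(mb, ma))
    stop("marker sets differ; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  N <- length(ma)
  ga <- .genome_adjacencies(a)
  gb <- .genome_adjacencies(b)
  # neighbor maps: per genome, each extremity has at most one partner
  nb <- function(gg) {
    v <- rep(NA_integer_, 2L * max(ma))
    if (nrow(gg$adj)) {
      v[gg$adj[, 1]] <- gg$adj[, 2]
      v[gg$adj[, 2]] <- gg$adj[, 1]
    }
    v
  }
  na_ <- nb(ga); nb_ <- nb(gb)
  ext_ids <- sort(unlist(lapply(ma, function(m) c(2L * m - 1L, 2L * m))))
  seen <- logical(2L * max(ma))

  # Alternating walk from `start`, taking an a-edge first iff `first_a`.
  # Edges alternate a/b, so the walk either hits a missing edge (path) or
  # returns to `start` (cycle).
  walk <- function(start, first_a) {
    vertices <- start; edges <- 0L; cur <- start; use_a <- first_a
    repeat {
      nxt <- if (use_a) na_[cur] else nb_[cur]
      if (is.na(nxt))
        return(list(vertices = vertices, edges = edges, closed = FALSE))
      edges <- edges + 1L
      if (nxt == start)
        return(list(vertices = vertices, edges = edges, closed = TRUE))
      vertices <- c(vertices, nxt)
      cur <- nxt
      use_a <- !use_a
    }
  }

  C <- 0L; I <- 0L
  components <- list()
  # paths first: start every walk at an endpoint (an extremity that is a
  # telomere in one of the genomes). A walk over e edges spans e + 1
  # extremities, i.e. e + 1 adjacency/telomere vertices of the standard
  # adjacency graph, so the "odd path" count of the distance formula is the
  # number of walks with an EVEN edge count (an extremity that is a telomere
  # in both genomes is such a path, with zero edges).
  for (e in ext_ids) {
    if (seen[e] || (!is.na(na_[e]) && !is.na(nb_[e]))) next
    w <- walk(e, first_a = !is.na(na_[e]))
    seen[w$vertices] <- TRUE
    if (w$edges %% 2L == 0L) I <- I + 1L
    components[[length(components) + 1L]] <- c(w, type = "path")
  }
  # everything unvisited now lies on cycles
  for (e in ext_ids) {
    if (seen[e]) next
    w <- walk(e, first_a = TRUE)
    seen[w$vertices] <- TRUE
    C <- C + 1L
    components[[length(components) + 1L]] <- c(w, type = "cycle")
  }
  list(N = N, C = C, I = I, components = components)
}

#' Double-cut-and-join distance
#'
#' The minimum number of DCJ operations (cut two adjacencies or telomeres,
#' rejoin the four ends differently) transforming one signed gene order into
#' another, computed from the adjacency graph as `N - (C + I/2)` where `N`
#' is the marker count, `C` the number of cycles and `I` the number of
#' odd-length paths. Symmetric and deterministic.
#'
#' @param a,b [signed_gene_order()] objects over the same marker set.
#' @return Non-negative integer distance.
#' @export
dcj_distance <- function(a, b) {
  g <- adjacency_graph(a, b)
  as.integer(g$N - (g$C + g$I / 2))
}

# --- BFS oracle ------------------------------------------------------------

# state: partner vector over extremities 1..2N (0 = telomere); canonical
# serialization for hashing
.state_of <- function(g, N) {
  gg <- .genome_adjacencies(g)
  v <- rep(0L, 2L * N)
  if (nrow(gg$adj)) { v[gg$adj[, 1]] <- gg$adj[, 2]; v[gg$adj[, 2]] <- gg$adj[, 1] }
  v
}

.state_key <- function(v) paste(v, collapse = ",")

# all states one DCJ move from partner-vector v
.dcj_neighbors <- function(v) {
  n2 <- length(v)
  adj <- which(v > seq_len(n2))   # each adjacency once, indexed by smaller end
  adj_pairs <- lapply(adj, function(p) c(p, v[p]))
  telo <- which(v == 0L)
  out <- list()
  push <- function(w) out[[length(out) + 1L]] <<- w
  np <- length(adj_pairs)
  # two adjacencies -> two rejoinings
  if (np >= 2L) for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    p <- adj_pairs[[i]]; q <- adj_pairs[[j]]
    w <- v; w[p[1]] <- q[1]; w[q[1]] <- p[1]; w[p[2]] <- q[2]; w[q[2]] <- p[2]
    push(w)
    w <- v; w[p[1]] <- q[2]; w[q[2]] <- p[1]; w[p[2]] <- q[1]; w[q[1]] <- p[2]
    push(w)
  }
  # adjacency + telomere -> two rejoinings
  for (pp in adj_pairs) for (t in telo) {
    w <- v; w[pp[1]] <- t; w[t] <- pp[1]; w[pp[2]] <- 0L
    push(w)
    w <- v; w[pp[2]] <- t; w[t] <- pp[2]; w[pp[1]] <- 0L
    push(w)
  }
  # adjacency -> split into two telomeres
  for (pp in adj_pairs) {
    w <- v; w[pp[1]] <- 0L; w[pp[2]] <- 0L
    push(w)
  }
  # two telomeres -> join
  nt <- length(telo)
  if (nt >= 2L) for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    w <- v; w[telo[i]] <- telo[j]; w[telo[j]] <- telo[i]
    push(w)
  }
  out
}

#' Brute-force DCJ distance by breadth-first search
#'
#' Independent oracle for [dcj_distance()]: explores the graph of all DCJ
#' moves (adjacency/telomere cuts and rejoinings) from genome `a` until it
#' reaches genome `b`, returning the shortest path length. Exponential in
#' `N`; refuses marker sets larger than `max_n`.
#'
#' @param a,b [signed_gene_order()] objects over the same marker set.
#' @param max_n Refusal threshold on the marker count.
#' @return Non-negative integer distance.
#' @export
dcj_distance_bruteforce <- function(a, b, max_n = 8L) {
  N <- length(unlist(a$chromosomes))
  if (N > max_n) stop("N = ", N, " exceeds max_n = ", max_n)
  if (!identical(sort(abs(unlist(a$chromosomes))),
                 sort(abs(unlist(b$chromosomes)))))
    stop("marker sets differ")
  v0 <- .state_of(a, N)
  vt <- .state_of(b, N)
  if (identical(v0, vt)) return(0L)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(.state_key(v0), TRUE, envir = visited)
  frontier <- list(v0)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (v in frontier) {
      for (w in .dcj_neighbors(v)) {
        if (identical(w, vt)) return(d)
        k <- .state_key(w)
        if (!exists(k, envir = visited, inherits = FALSE)) {
          assign(k, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    if (length(nxt) == 0L) stop("target unreachable (should not happen)")
    frontier <- nxt
  }
}
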