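## Minimal Turtle reader/writer for the supported fragment.  Both sides
## speak a common triple table: data.frame(s, p, o, o_iri) where blank
## nodes are skolemized to "_:b<N>" in document order so parses (and hence
## parse reports) are reproducible.

ttlEscape <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    x <- gsub("\"", "\\\"", x, fixed = TRUE)
    x <- gsub("\n", "\\n", x, fixed = TRUE)
    x <- gsub("\r", "\\r", x, fixed = TRUE)
    x <- gsub("\t", "\\t", x, fixed = TRUE)
    x
}

ttlUnescape <- function(x) {
    out <- character(length(x))
    for (i in seq_along(x)) {
        s <- x[i]
        res <- ""
        j <- 1L; n <- nchar(s)
        while (j <= n) {
            ch <- substr(s, j, j)
            if (ch == "\\" && j < n) {
                nxt <- substr(s, j + 1L, j + 1L)
                res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                                          "\"" = "\"", "\\" = "\\", nxt))
                j <- j + 2L
            } else {
                res <- paste0(res, ch)
                j <- j + 1L
            }
        }
        out[i] <- res
    }
    out
}

## tokenizer: IRIs, prefixed names, quoted strings (with escapes),
## punctuation, comments.  Single-pass via one alternation regex so large
## documents tokenize in linear time; comments are dropped, and datatype /
## language suffixes on literals are stripped (the fragment only carries
## plain literals).
ttlTokenize <- function(text) {
    pattern <- paste0(
        "(\"(?:[^\"\\\\]|\\\\.)*\"",                     # quoted string ...
        "(?:\\^\\^(?:<[^>]*>|[A-Za-z][A-Za-z0-9:_]*)",   # ... ^^datatype
        "|@[A-Za-z][A-Za-z0-9-]*)?)",                    # ... @lang
        "|(<[^>]*>)",                                    # IRI
        "|(#[^\n]*)",                                    # comment
        "|([;,\\[\\]()])",                               # punctuation
        "|(\\.(?=[ \t\r\n]|$))",                         # statement dot
        "|([^ \t\r\n;,\\[\\]()\"<#]+)")                  # bare word
    m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(character(0))
    tokens <- regmatches(text, list(m))[[1L]]
    tokens <- tokens[!startsWith(tokens, "#")]
    ## strip datatype/language suffixes from literal tokens
    lit <- startsWith(tokens, "\"")
    tokens[lit] <- vapply(tokens[lit], function(tk) {
        ## keep through the closing quote only
        i <- 2L
        n <- nchar(tk)
        while (i <= n) {
            ch <- substr(tk, i, i)
            if (ch == "\\") { i <- i + 2L; next }
            if (ch == "\"") break
            i <- i + 1L
        }
        substr(tk, 1L, i)
    }, character(1), USE.NAMES = FALSE)
    ## split statement-terminating dots glued to bare words
    glued <- !lit & nchar(tokens) > 1L & endsWith(tokens, ".") &
        !startsWith(tokens, "<")
    if (any(glued)) {
        out <- vector("list", length(tokens))
        for (i in seq_along(tokens)) {
            out[[i]] <- if (glued[i]) c(sub("\\.$", "", tokens[i]), ".")
                        else tokens[i]
        }
        tokens <- unlist(out)
    }
    tokens
}

ttlParse <- function(text) {
    toks <- ttlTokenize(text)
    pos <- 1L
    prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
    bcount <- 0L
    triples <- list()

    peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
    advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
    expect <- function(t) {
        got <- advance()
        if (!identical(got, t)) {
            stop("turtle parse error: expected '", t, "' but got '", got,
                 "' at token ", pos - 1L)
        }
    }
    emit <- function(s, p, o, o_iri) {
        triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o, o_iri = o_iri)
    }
    newBnode <- function() { bcount <<- bcount + 1L; paste0("_:b", bcount) }
    resolve <- function(tok) {
        if (is.na(tok)) stop("turtle parse error: unexpected end of input")
        if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
        if (tok == "a") return(paste0(prefixes[["rdf"]], "type"))
        if (startsWith(tok, "_:")) return(tok)
        m <- regexpr(":", tok, fixed = TRUE)
        if (m < 0) stop("turtle parse error: cannot resolve token '", tok, "'")
        pre <- substr(tok, 1L, m - 1L)
        loc <- substr(tok, m + 1L, nchar(tok))
        if (!(pre %in% names(prefixes))) {
            stop("turtle parse error: unknown prefix '", pre, "'")
        }
        paste0(prefixes[[pre]], loc)
    }

    parseObject <- function(s, p) {
        tok <- peek()
        if (identical(tok, "[")) {
            advance()
            b <- newBnode()
            emit(s, p, b, TRUE)
            if (!identical(peek(), "]")) parsePOList(b)
            expect("]")
        } else if (identical(tok, "(")) {
            advance()
            items <- list()
            while (!identical(peek(), ")")) {
                itok <- advance()
                if (startsWith(itok, "\"")) {
                    items[[length(items) + 1L]] <-
                        list(v = ttlUnescape(substr(itok, 2L, nchar(itok) - 1L)),
                             iri = FALSE)
                } else {
                    items[[length(items) + 1L]] <- list(v = resolve(itok), iri = TRUE)
                }
            }
            expect(")")
            rdf <- prefixes[["rdf"]]
            if (length(items) == 0L) {
                emit(s, p, paste0(rdf, "nil"), TRUE)
            } else {
                head <- newBnode()
                emit(s, p, head, TRUE)
                cur <- head
                for (k in seq_along(items)) {
                    emit(cur, paste0(rdf, "first"), items[[k]]$v, items[[k]]$iri)
                    if (k < length(items)) {
                        nxt <- newBnode()
                        emit(cur, paste0(rdf, "rest"), nxt, TRUE)
                        cur <- nxt
                    } else {
                        emit(cur, paste0(rdf, "rest"), paste0(rdf, "nil"), TRUE)
                    }
                }
            }
        } else if (!is.na(tok) && startsWith(tok, "\"")) {
            advance()
            emit(s, p, ttlUnescape(substr(tok, 2L, nchar(tok) - 1L)), FALSE)
        } else {
            emit(s, p, resolve(advance()), TRUE)
        }
    }

    parsePOList <- function(s) {
        repeat {
            p <- resolve(advance())
            repeat {
                parseObject(s, p)
                if (identical(peek(), ",")) { advance(); next }
                break
            }
            if (identical(peek(), ";")) {
                advance()
                if (identical(peek(), "]") || identical(peek(), ".")) break
                next
            }
            break
        }
    }

    while (pos <= length(toks)) {
        tok <- peek()
        if (identical(tok, "@prefix") || identical(tolower(tok), "prefix")) {
            advance()
            decl <- advance()   # "pre:"
            iri <- advance()
            pre <- sub(":$", "", decl)
            prefixes[[pre]] <- substr(iri, 2L, nchar(iri) - 1L)
            if (identical(peek(), ".")) advance()
            next
        }
        if (identical(tok, "@base")) {
            advance(); advance()
            if (identical(peek(), ".")) advance()
            next
        }
        ## subject
        s <- if (identical(tok, "[")) {
            advance()
            b <- newBnode()
            if (!identical(peek(), "]")) parsePOList(b)
            expect("]")
            b
        } else {
            resolve(advance())
        }
        parsePOList(s)
        expect(".")
    }

    if (length(triples) == 0L) {
        return(data.frame(s = character(0), p = character(0), o = character(0),
                          o_iri = logical(0), stringsAsFactors = FALSE))
    }
    data.frame(s = vapply(triples, `[[`, character(1), "s"),
               p = vapply(triples, `[[`, character(1), "p"),
               o = vapply(triples, `[[`, character(1), "o"),
               o_iri = vapply(triples, `[[`, logical(1), "o_iri"),
               stringsAsFactors = FALSE)
}

## serialize a triple table grouped by subject
ttlSerialize <- function(triples, prefixes) {
    shorten <- function(iri) {
        for (p in names(prefixes)) {
            base <- prefixes[[p]]
            if (startsWith(iri, base)) {
                loc <- substr(iri, nchar(base) + 1L, nchar(iri))
                if (grepl("^[A-Za-z0-9_.-]+$", loc) && !grepl("^\\.|\\.$", loc)) {
                    return(paste0(p, ":", loc))
                }
            }
        }
        paste0("<", iri, ">")
    }
    term <- function(o, iri) {
        if (iri) {
            if (startsWith(o, "_:")) o else shorten(o)
        } else {
            paste0("\"", ttlEscape(o), "\"")
        }
    }
    out <- vapply(names(prefixes), function(p)
        paste0("@prefix ", p, ": <", prefixes[[p]], "> ."), character(1))
    out <- c(out, "")
    for (s in unique(triples$s)) {
        rows <- triples[triples$s == s, , drop = FALSE]
        subj <- if (startsWith(s, "_:")) s else shorten(s)
        lines <- character(0)
        for (p in unique(rows$p)) {
            objs <- rows[rows$p == p, , drop = FALSE]
            rendered <- mapply(term, objs$o, objs$o_iri, USE.NAMES = FALSE)
            lines <- c(lines, paste0("    ", shorten(p), " ",
                                     paste(rendered, collapse = ", ")))
        }
        out <- c(out, paste0(subj, "\n", paste(lines, collapse = " ;\n"), " ."),
                 "")
    }
    paste0(paste(out, collapse = "\n"), "\n")
}
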