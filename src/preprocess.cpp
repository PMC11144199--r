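#include <Rcpp.h>
using namespace Rcpp;

// Adapter + quality trimming of one read set.
//
// The adapter is located as the longest suffix-anchored match of the adapter
// prefix: the matched region is a suffix of the read and a prefix of the
// adapter, allowing at most one mismatch per 8 matched bases; matches shorter
// than 8 bases (minimum 3, at the extreme 3' end) must be exact. After
// adapter removal, trailing cycles with quality below the floor are removed.
// [[Rcpp::export(name = ".trim_reads_cpp")]]
List trim_reads_cpp(CharacterVector seqs, CharacterVector quals,
                    std::string adapter, int quality_floor) {
    const int n = seqs.size();
    CharacterVector oseq(n), oqual(n);
    const int m = adapter.size();
    const char qmin = (char)(quality_floor + 33);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string q = as<std::string>(quals[i]);
        if (s.size() != q.size())
            stop("sequence/quality length mismatch in read %d", i + 1);
        int len = s.size();
        // scan candidate adapter starts left to right: the first (longest)
        // passing match wins
        int first = len - m; if (first < 0) first = 0;
        for (int p = first; p <= len - 3; ++p) {
            int k = len - p;             // match length (<= m)
            int allowed = (k >= 8) ? k / 8 : 0;
            int mm = 0;
            for (int j = 0; j < k; ++j) {
                if (s[p + j] != adapter[j] && ++mm > allowed) break;
            }
            if (mm <= allowed) { len = p; break; }
        }
        // 3' quality trimming
        while (len > 0 && q[len - 1] < qmin) --len;
        oseq[i] = s.substr(0, len);
        oqual[i] = q.substr(0, len);
    }
    return List::create(_["seq"] = oseq, _["qual"] = oqual);
}

// FLASH-style overlap merging of mate pairs.
//
// seq2rc / qual2rev must already be the reverse complement of read 2 and its
// reversed quality string. Candidate overlaps o run from min(len1, len2) down
// to min_overlap; the candidate minimising the mismatch fraction wins, ties
// broken by the larger o; it is accepted only if its mismatch fraction is
// <= max_mismatch_frac. Overlap bases take the higher-quality mate's base
// (ties -> read 1) and the max of the two qualities.
// [[Rcpp::export(name = ".stitch_reads_cpp")]]
List stitch_reads_cpp(CharacterVector seq1, CharacterVector qual1,
                      CharacterVector seq2rc, CharacterVector qual2rev,
                      int min_overlap, double max_mismatch_frac) {
    const int n = seq1.size();
    IntegerVector overlap(n);
    CharacterVector mseq(n), mqual(n);
    for (int i = 0; i < n; ++i) {
        const std::string s1 = as<std::string>(seq1[i]);
        const std::string q1 = as<std::string>(qual1[i]);
        const std::string s2 = as<std::string>(seq2rc[i]);
        const std::string q2 = as<std::string>(qual2rev[i]);
        const int l1 = s1.size(), l2 = s2.size();
        int best_o = 0;
        double best_frac = 2.0;
        const int omax = l1 < l2 ? l1 : l2;
        for (int o = omax; o >= min_overlap; --o) {
            int mm = 0;
            const int off = l1 - o;
            for (int j = 0; j < o; ++j)
                if (s1[off + j] != s2[j]) ++mm;
            double frac = (double)mm / o;
            if (frac < best_frac) { best_frac = frac; best_o = o; }
        }
        if (best_o >= min_overlap && best_frac <= max_mismatch_frac) {
            const int o = best_o, off = l1 - o;
            std::string ms = s1.substr(0, off);
            std::string mq = q1.substr(0, off);
            ms.reserve(l1 + l2 - o);
            for (int j = 0; j < o; ++j) {
                if (q2[j] > q1[off + j]) {
                    ms.push_back(s2[j]);
                } else {
                    ms.push_back(s1[off + j]);
                }
                mq.push_back(q1[off + j] > q2[j] ? q1[off + j] : q2[j]);
            }
            ms.append(s2, o, std::string::npos);
            mq.append(q2, o, std::string::npos);
            overlap[i] = o;
            mseq[i] = ms;
            mqual[i] = mq;
        } else {
            overlap[i] = 0;
            mseq[i] = NA_STRING;
            mqual[i] = NA_STRING;
        }
    }
    return List::create(_["overlap"] = overlap, _["seq"] = mseq,
                        _["qual"] = mqual);
}
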