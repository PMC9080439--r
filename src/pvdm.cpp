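// Distributed-memory paragraph vectors (PV-DM) with negative sampling.
// Single-threaded by design: fixed seed => bit-reproducible training.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64: small, fast, full-period generator; independent of R's RNG so
// training does not disturb the user's random stream.
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double uniform() {  // [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Cumulative unigram^0.75 table; negatives drawn by binary search.
std::vector<double> build_cumtable(const IntegerVector& counts) {
  std::vector<double> cum(counts.size());
  double acc = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    acc += std::pow((double)counts[i], 0.75);
    cum[i] = acc;
  }
  return cum;
}

inline int sample_negative(const std::vector<double>& cum, Rng& rng) {
  double r = rng.uniform() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
}

void init_uniform(double* m, int n, int dim, Rng& rng) {
  for (int i = 0; i < n * dim; ++i)
    m[i] = (rng.uniform() - 0.5) / dim;
}

// One PV-DM training pass over a document at position t: the input is the
// mean of the paragraph vector and the window word vectors; the center word
// is predicted against `negative` noise words. Gradients flow to syn1neg,
// to each contributing word vector (unless frozen) and to the paragraph
// vector.
void train_position(const std::vector<int>& doc, int t, int window,
                    double* docvec, double* syn0, double* syn1neg,
                    const std::vector<double>& cum, int dim, int negative,
                    double lr, bool freeze_words, Rng& rng,
                    std::vector<double>& neu1, std::vector<double>& neu1e) {
  int lo = std::max(0, t - window);
  int hi = std::min((int)doc.size() - 1, t + window);
  std::fill(neu1.begin(), neu1.end(), 0.0);
  std::fill(neu1e.begin(), neu1e.end(), 0.0);
  int m = 1;
  for (int j = lo; j <= hi; ++j) {
    if (j == t) continue;
    const double* wv = syn0 + (size_t)doc[j] * dim;
    for (int d = 0; d < dim; ++d) neu1[d] += wv[d];
    ++m;
  }
  for (int d = 0; d < dim; ++d) neu1[d] = (neu1[d] + docvec[d]) / m;

  int w = doc[t];
  for (int k = 0; k <= negative; ++k) {
    int target;
    double label;
    if (k == 0) { target = w; label = 1.0; }
    else {
      target = sample_negative(cum, rng);
      if (target == w) continue;
      label = 0.0;
    }
    double* out = syn1neg + (size_t)target * dim;
    double f = 0.0;
    for (int d = 0; d < dim; ++d) f += neu1[d] * out[d];
    double g = (label - sigmoid(f)) * lr;
    for (int d = 0; d < dim; ++d) neu1e[d] += g * out[d];
    if (!freeze_words) {  // inference locks the output layer as well
      for (int d = 0; d < dim; ++d) out[d] += g * neu1[d];
    }
  }
  for (int d = 0; d < dim; ++d) docvec[d] += neu1e[d];
  if (!freeze_words) {
    for (int j = lo; j <= hi; ++j) {
      if (j == t) continue;
      double* wv = syn0 + (size_t)doc[j] * dim;
      for (int d = 0; d < dim; ++d) wv[d] += neu1e[d];
    }
  }
}

} // namespace

// [[Rcpp::export]]
List pvdm_train_cpp(List docs, IntegerVector counts, int dim, int window,
                    double alpha, double min_alpha, int negative, int epochs,
                    double seed) {
  int n_docs = docs.size();
  int vocab = counts.size();
  Rng rng((uint64_t)seed);

  std::vector<std::vector<int>> corpus(n_docs);
  long long total_words = 0;
  for (int i = 0; i < n_docs; ++i) {
    IntegerVector v = docs[i];
    corpus[i].assign(v.begin(), v.end());
    total_words += v.size();
  }

  NumericMatrix syn0(dim, vocab), syn1neg(dim, vocab), docvecs(dim, n_docs);
  init_uniform(REAL(syn0), vocab, dim, rng);
  init_uniform(REAL(docvecs), n_docs, dim, rng);
  // syn1neg starts at zero (standard negative-sampling init)

  std::vector<double> cum = build_cumtable(counts);
  std::vector<double> neu1(dim), neu1e(dim);

  long long processed = 0;
  long long grand_total = total_words * (long long)epochs;
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < n_docs; ++i) {
      const std::vector<int>& doc = corpus[i];
      double* dv = REAL(docvecs) + (size_t)i * dim;
      for (size_t t = 0; t < doc.size(); ++t) {
        double frac = grand_total > 0 ? (double)processed / grand_total : 0.0;
        double lr = alpha - (alpha - min_alpha) * frac;
        if (lr < min_alpha) lr = min_alpha;
        train_position(doc, (int)t, window, dv, REAL(syn0), REAL(syn1neg),
                       cum, dim, negative, lr, false, rng, neu1, neu1e);
        ++processed;
      }
    }
  }
  return List::create(_["word_vectors"] = syn0,
                      _["output_weights"] = syn1neg,
                      _["doc_vectors"] = docvecs);
}

// [[Rcpp::export]]
NumericVector pvdm_infer_cpp(IntegerVector words, NumericMatrix syn0,
                             NumericMatrix syn1neg, IntegerVector counts,
                             int window, double alpha, double min_alpha,
                             int negative, int epochs, double seed) {
  int dim = syn0.nrow();
  Rng rng((uint64_t)seed);
  NumericVector docvec(dim);
  init_uniform(REAL(docvec), 1, dim, rng);

  std::vector<int> doc(words.begin(), words.end());
  if (doc.empty() || epochs < 1) return docvec;

  // word and output weights are frozen; only the new paragraph vector moves
  std::vector<double> cum = build_cumtable(counts);
  std::vector<double> neu1(dim), neu1e(dim);

  long long processed = 0;
  long long grand_total = (long long)doc.size() * epochs;
  for (int e = 0; e < epochs; ++e) {
    for (size_t t = 0; t < doc.size(); ++t) {
      double frac = (double)processed / grand_total;
      double lr = alpha - (alpha - min_alpha) * frac;
      if (lr < min_alpha) lr = min_alpha;
      train_position(doc, (int)t, window, REAL(docvec), REAL(syn0),
                     REAL(syn1neg), cum, dim, negative, lr, true, rng,
                     neu1, neu1e);
      ++processed;
    }
  }
  return docvec;
}
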