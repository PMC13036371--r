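// 8-bit photometric perturbation kernels. All arithmetic is defined on
// integer pixel values in [0,255]; every operator rounds half away from
// zero and clips back to [0,255] so results are bit-reproducible across
// platforms. Arrays are column-major H x W x 3 (R array layout).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int round_half_away(double x) {
  return (x >= 0.0) ? (int)std::floor(x + 0.5) : (int)std::ceil(x - 0.5);
}

static inline int clip8(int v) { return v < 0 ? 0 : (v > 255 ? 255 : v); }

static inline int round_clip(double x) { return clip8(round_half_away(x)); }

// integer luma per the Rec.601 weights used by 8-bit grayscale conversion
static inline int luma_int(int r, int g, int b) {
  return round_half_away((299.0 * r + 587.0 * g + 114.0 * b) / 1000.0);
}

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
IntegerVector cpp_resize_bilinear(IntegerVector img, int h, int w, int side) {
  if (h <= 0 || w <= 0) stop("zero-sized image");
  if (side <= 0) stop("target side must be positive");
  if (h == side && w == side) return clone(img);
  IntegerVector out(side * side * 3);
  out.attr("dim") = IntegerVector::create(side, side, 3);
  double sy = (double)h / side, sx = (double)w / side;
  for (int c = 0; c < 3; ++c) {
    const int off_in = c * h * w, off_out = c * side * side;
    for (int j = 0; j < side; ++j) {
      double xs = (j + 0.5) * sx - 0.5;
      if (xs < 0) xs = 0;
      if (xs > w - 1) xs = w - 1;
      int x0 = (int)std::floor(xs);
      int x1 = x0 + 1 < w ? x0 + 1 : w - 1;
      double fx = xs - x0;
      for (int i = 0; i < side; ++i) {
        double ys = (i + 0.5) * sy - 0.5;
        if (ys < 0) ys = 0;
        if (ys > h - 1) ys = h - 1;
        int y0 = (int)std::floor(ys);
        int y1 = y0 + 1 < h ? y0 + 1 : h - 1;
        double fy = ys - y0;
        double v =
          (1 - fy) * ((1 - fx) * img[off_in + y0 + h * x0] +
                      fx * img[off_in + y0 + h * x1]) +
          fy * ((1 - fx) * img[off_in + y1 + h * x0] +
                fx * img[off_in + y1 + h * x1]);
        out[off_out + i + side * j] = round_clip(v);
      }
    }
  }
  return out;
}

// kind: 1 brightness, 2 contrast, 3 saturation, 4 sharpness.
// out = round_clip((1 - factor) * degenerate + factor * original), where the
// degenerate image is all-black (brightness), the uniform rounded mean-luma
// image (contrast), the per-pixel rounded luma replicated to 3 channels
// (saturation), or a rounded 3x3-smoothed copy with the border ring copied
// from the original (sharpness).
// [[Rcpp::export(name = ".cpp_enhance")]]
IntegerVector cpp_enhance(IntegerVector img, int h, int w, int kind,
                          double factor) {
  if (factor < 0) stop("enhancement factor must be non-negative");
  int n = h * w;
  IntegerVector out(n * 3);
  out.attr("dim") = IntegerVector::create(h, w, 3);
  if (kind == 1) {                       // brightness: degenerate = 0
    for (int k = 0; k < 3 * n; ++k) out[k] = round_clip(factor * img[k]);
    return out;
  }
  if (kind == 2 || kind == 3) {
    std::vector<int> L(n);
    for (int p = 0; p < n; ++p)
      L[p] = luma_int(img[p], img[n + p], img[2 * n + p]);
    if (kind == 2) {                     // contrast: degenerate = mean luma
      double s = 0;
      for (int p = 0; p < n; ++p) s += L[p];
      int M = round_half_away(s / n);
      for (int c = 0; c < 3; ++c)
        for (int p = 0; p < n; ++p)
          out[c * n + p] = round_clip((1 - factor) * M + factor * img[c * n + p]);
    } else {                             // saturation: degenerate = luma image
      for (int c = 0; c < 3; ++c)
        for (int p = 0; p < n; ++p)
          out[c * n + p] =
            round_clip((1 - factor) * L[p] + factor * img[c * n + p]);
    }
    return out;
  }
  if (kind == 4) {                       // sharpness: degenerate = smoothed
    // 3x3 kernel [[1,1,1],[1,5,1],[1,1,1]] / 13 on the interior;
    // border ring of the degenerate copy equals the original
    for (int c = 0; c < 3; ++c) {
      const int off = c * n;
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          int deg;
          if (i == 0 || j == 0 || i == h - 1 || j == w - 1) {
            deg = img[off + i + h * j];
          } else {
            int s = 5 * img[off + i + h * j];
            s += img[off + (i - 1) + h * (j - 1)] + img[off + (i - 1) + h * j] +
                 img[off + (i - 1) + h * (j + 1)] + img[off + i + h * (j - 1)] +
                 img[off + i + h * (j + 1)] + img[off + (i + 1) + h * (j - 1)] +
                 img[off + (i + 1) + h * j] + img[off + (i + 1) + h * (j + 1)];
            deg = round_half_away(s / 13.0);
          }
          out[off + i + h * j] =
            round_clip((1 - factor) * deg + factor * img[off + i + h * j]);
        }
      }
    }
    return out;
  }
  stop("unknown enhancement kind");
}

// 8-bit RGB -> HSV, all three channels on [0,255]
static inline void rgb_to_hsv8(int r, int g, int b, int &H, int &S, int &V) {
  int mx = std::max(r, std::max(g, b));
  int mn = std::min(r, std::min(g, b));
  int d = mx - mn;
  V = mx;
  S = (mx == 0) ? 0 : round_half_away(255.0 * d / mx);
  if (d == 0) {
    H = 0;
    return;
  }
  double hh;
  if (mx == r)
    hh = (double)(g - b) / d;   // in [-1, 1], wrapped below
  else if (mx == g)
    hh = (double)(b - r) / d + 2.0;
  else
    hh = (double)(r - g) / d + 4.0;
  if (hh < 0) hh += 6.0;
  H = round_half_away(hh / 6.0 * 255.0) % 256;
}

// 8-bit HSV -> RGB (hexcone)
static inline void hsv8_to_rgb(int H, int S, int V, int &r, int &g, int &b) {
  if (S == 0) {
    r = g = b = V;
    return;
  }
  double hh = (double)H / 255.0 * 6.0;
  int sector = ((int)std::floor(hh)) % 6;
  double f = hh - std::floor(hh);
  double s = (double)S / 255.0;
  int p = round_half_away(V * (1.0 - s));
  int q = round_half_away(V * (1.0 - f * s));
  int t = round_half_away(V * (1.0 - (1.0 - f) * s));
  switch (sector) {
  case 0: r = V; g = t; b = p; break;
  case 1: r = q; g = V; b = p; break;
  case 2: r = p; g = V; b = t; break;
  case 3: r = p; g = q; b = V; break;
  case 4: r = t; g = p; b = V; break;
  default: r = V; g = p; b = q; break;
  }
}

// [[Rcpp::export(name = ".cpp_rgb_to_hsv8")]]
IntegerVector cpp_rgb_to_hsv8(IntegerVector img, int h, int w) {
  int n = h * w;
  IntegerVector out(n * 3);
  out.attr("dim") = IntegerVector::create(h, w, 3);
  for (int p = 0; p < n; ++p) {
    int H, S, V;
    rgb_to_hsv8(img[p], img[n + p], img[2 * n + p], H, S, V);
    out[p] = H;
    out[n + p] = S;
    out[2 * n + p] = V;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_hsv8_to_rgb")]]
IntegerVector cpp_hsv8_to_rgb(IntegerVector img, int h, int w) {
  int n = h * w;
  IntegerVector out(n * 3);
  out.attr("dim") = IntegerVector::create(h, w, 3);
  for (int p = 0; p < n; ++p) {
    int r, g, b;
    hsv8_to_rgb(img[p], img[n + p], img[2 * n + p], r, g, b);
    out[p] = r;
    out[n + p] = g;
    out[2 * n + p] = b;
  }
  return out;
}

// H_new = (H_old + round_half_away(delta_h * 255)) mod 256; S, V untouched
// [[Rcpp::export(name = ".cpp_shift_hue")]]
IntegerVector cpp_shift_hue(IntegerVector img, int h, int w, double delta_h) {
  int n = h * w;
  int shift = round_half_away(delta_h * 255.0);
  if (shift % 256 == 0) {             // zero shift: byte-exact identity
    IntegerVector out = clone(img);
    out.attr("dim") = IntegerVector::create(h, w, 3);
    return out;
  }
  IntegerVector out(n * 3);
  out.attr("dim") = IntegerVector::create(h, w, 3);
  for (int p = 0; p < n; ++p) {
    int H, S, V, r, g, b;
    rgb_to_hsv8(img[p], img[n + p], img[2 * n + p], H, S, V);
    H = ((H + shift) % 256 + 256) % 256;
    hsv8_to_rgb(H, S, V, r, g, b);
    out[p] = r;
    out[n + p] = g;
    out[2 * n + p] = b;
  }
  return out;
}
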