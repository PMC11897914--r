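# 25-band near-infrared snapshot mosaic camera, 659-947 nm, 5x5 tile.
name: NIR
band_peaks: [659, 668, 687, 700, 711, 728, 739, 752, 766, 779, 788, 802, 813, 826, 840, 850, 862, 876, 888, 896, 910, 918, 928, 939, 947]
band_fwhm: [6, 5, 6, 7, 7, 8, 6, 8, 8, 7, 8, 8, 8, 8, 8, 10, 10, 11, 14, 13, 16, 16, 17, 19, 17]
mosaic_shape: [5, 5]
sensor_shape: [1088, 2048]
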