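# 16-band visible-range snapshot mosaic camera, 460-600 nm, 4x4 tile.
name: VIS
band_peaks: [460, 469, 475, 484, 496, 504, 514, 526, 532, 546, 550, 564, 570, 581, 589, 596]
band_fwhm: [9, 10, 16, 10, 16, 19, 15, 19, 17, 15, 15, 16, 13, 18, 17, 16]
mosaic_shape: [4, 4]
sensor_shape: [1088, 2048]
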