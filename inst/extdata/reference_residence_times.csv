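# Reference residence times (h), mean and SD over two animals, from a
# published whole-body PET dosimetry study of an F-18 NIS tracer
# (tetrafluoroborate) in non-human primates; human 70-kg model bookkeeping.
# "remainder" is T1/2/ln2 minus the sum of the measured organs.
organ,tau_h,sd_h
brain,1.21E-02,3.7E-03
stomach,1.81E-01,5.3E-02
heart_contents,2.31E-02,3.9E-03
kidneys,2.44E-02,8.4E-04
lungs,6.79E-02,1.2E-02
thyroid,4.68E-03,6.3E-06
urinary_bladder_contents,7.66E-02,3.3E-02
spleen,4.18E-03,7.0E-06
red_marrow,8.65E-02,1.4E-04
parotid_gland,4.68E-03,2.5E-03
submandibular_gland,1.75E-03,1.1E-03
remainder,2.14E+00,1.0E-01
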