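# Protected abbreviations for the sentence splitter: a break candidate whose
# preceding text ends with one of these strings is suppressed.
# Species-style single-capital abbreviations ("E. coli") need no entry here:
# a break is only proposed before an uppercase letter or digit.
et al.
Fig.
Figs.
Tab.
i.e.
e.g.
vs.
cf.
ca.
approx.
no.
No.
Dr.
Prof.
St.
Mr.
Mrs.
Ms.
Inc.
Ltd.
Co.
Ref.
Eq.
Eqs.
Sec.
Vol.
pp.
ed.
eds.
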