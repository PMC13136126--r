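name,n,is3oxo,mz,rt
3-oxo-C6,6,TRUE,214,3.0
C6,6,FALSE,200,3.8
C7,7,FALSE,214,4.3
C8,8,FALSE,228,4.6
3-oxo-C10,10,TRUE,270,4.9
C10,10,FALSE,256,5.4
3-oxo-C12,12,TRUE,298,5.6
C12,12,FALSE,284,6.1
3-oxo-C14,14,TRUE,326,6.3
C14,14,FALSE,312,6.8
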