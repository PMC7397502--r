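Type	background_id
DEL.C.1.1	0
DEL.C.1.2	0.1
DEL.C.1.3	0
DEL.C.1.4	0
DEL.C.1.5	0
DEL.C.1.6+	0
DEL.T.1.1	0.05
DEL.T.1.2	0.15
DEL.T.1.3	0.2
DEL.T.1.4	0.15
DEL.T.1.5	0.1
DEL.T.1.6+	0
INS.C.1.0	0
INS.C.1.1	0
INS.C.1.2	0
INS.C.1.3	0
INS.C.1.4	0
INS.C.1.5+	0
INS.T.1.0	0
INS.T.1.1	0.15
INS.T.1.2	0.1
INS.T.1.3	0
INS.T.1.4	0
INS.T.1.5+	0
DEL.R.2.1	0
DEL.R.2.2	0
DEL.R.2.3	0
DEL.R.2.4	0
DEL.R.2.5	0
DEL.R.2.6+	0
DEL.R.3.1	0
DEL.R.3.2	0
DEL.R.3.3	0
DEL.R.3.4	0
DEL.R.3.5	0
DEL.R.3.6+	0
DEL.R.4.1	0
DEL.R.4.2	0
DEL.R.4.3	0
DEL.R.4.4	0
DEL.R.4.5	0
DEL.R.4.6+	0
DEL.R.5+.1	0
DEL.R.5+.2	0
DEL.R.5+.3	0
DEL.R.5+.4	0
DEL.R.5+.5	0
DEL.R.5+.6+	0
INS.R.2.0	0
INS.R.2.1	0
INS.R.2.2	0
INS.R.2.3	0
INS.R.2.4	0
INS.R.2.5+	0
INS.R.3.0	0
INS.R.3.1	0
INS.R.3.2	0
INS.R.3.3	0
INS.R.3.4	0
INS.R.3.5+	0
INS.R.4.0	0
INS.R.4.1	0
INS.R.4.2	0
INS.R.4.3	0
INS.R.4.4	0
INS.R.4.5+	0
INS.R.5+.0	0
INS.R.5+.1	0
INS.R.5+.2	0
INS.R.5+.3	0
INS.R.5+.4	0
INS.R.5+.5+	0
DEL.MH.2.1	0
DEL.MH.3.1	0
DEL.MH.3.2	0
DEL.MH.4.1	0
DEL.MH.4.2	0
DEL.MH.4.3	0
DEL.MH.5+.1	0
DEL.MH.5+.2	0
DEL.MH.5+.3	0
DEL.MH.5+.4	0
DEL.MH.5+.5+	0
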