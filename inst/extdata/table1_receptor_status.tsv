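subtype	er	her2	pr	n
Basal	-	-	-	45
Basal	-	+	-	4
Her2	-	-	-	1
Her2	-	+	-	29
Her2	+	-	-	1
Her2	+	-	+	3
Her2	+	+	-	5
Her2	+	+	+	3
LumA	-	-	-	1
LumA	+	-	+	30
LumA	+	+	+	9
LumB	-	-	-	1
LumB	+	-	+	36
LumB	+	+	-	4
LumB	+	+	+	12
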