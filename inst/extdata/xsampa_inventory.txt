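tS
dZ
ts
dz
jj
rr
p
b
t
d
k
g
m
n
J
N
f
v
T
s
z
S
Z
x
G
B
D
l
L
r
4
j
w
a
e
E
i
o
O
u
y
@
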