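# The bcs dialect accepted by beaconr

A model file is line-oriented. `//` starts a comment running to end of
line; `;` may be used as an additional line separator. A physical line is
joined with the next when it ends mid-expression (trailing `=`, `+`, `,`,
`.`, `*`, `->` or `||`) or when the next line starts with `||`, `+` or `.`.
Whitespace is otherwise insignificant except as a token separator.

Every non-empty logical line containing a top-level `=` is a definition; the
single final line without `=` is the initial system.

## EBNF

```
model        = { definition } , system ;
definition   = constant-def | process-def ;
constant-def = NAME , "=" , arith ;            (* RHS closed over earlier constants *)
process-def  = NAME , [ "[" , NAME , { "," , NAME } , "]" ] , "=" , term ;
system       = entry , { "||" , entry } ;
entry        = [ NUMBER , "*" ] , NAME , [ "[" , arith , { "," , arith } , "]" ] ;

term         = choice , { "||" , choice } ;                (* parallel, loosest *)
choice       = sequence , { "+" , sequence } ;
sequence     = unit , { "." , unit } ;                     (* prefix, tightest *)
unit         = [ "[" , gate , "]" , "->" ] , action        (* gated action *)
             | NAME , [ "[" , arith , { "," , arith } , "]" ] (* process call *)
             | "(" , term , ")" ;                          (* group; last in a chain *)

action       = "{" , body , "," , arith , "}" ;            (* final field is the rate *)
body         = NAME                                        (* local action label *)
             | "@" , channel , "!" , "[" , payload , "]"   (* handshake send *)
             | "@" , channel , "?" , "[" , sets , "]" , [ bindings ]  (* handshake receive *)
             | channel , "!" , "[" , payload , "]"         (* beacon launch *)
             | channel , "#" , "[" , payload , "]"         (* beacon kill *)
             | channel , "?" , "[" , sets , "]" , [ bindings ]        (* beacon receive *)
             | "~" , channel , "?" , "[" , sets , "]" ;    (* beacon check *)
channel      = arith , { "," , arith } ;
payload      = arith , { "," , arith } ;
sets         = set , { "," , set } ;
bindings     = "(" , NAME , { "," , NAME } , ")" ;

set          = sinter , { "U" , sinter } ;                 (* union, loosest *)
sinter       = ssub , { "I" , ssub } ;
ssub         = satom , { "\" , satom } ;                   (* subtraction, tightest *)
satom        = arith , [ ".." , arith ] | "(" , set , ")" ;

gate         = gand , { "|" , gand } ;
gand         = gnot , { "&" , gnot } ;
gnot         = "~" , gnot | cmp | "(" , gate , ")" ;
cmp          = arith , ( "<=" | "<" | ">=" | ">" | "==" | "!=" ) , arith ;

arith        = mul , { ( "+" | "-" ) , mul } ;
mul          = unary , { ( "*" | "/" ) , unary } ;
unary        = "-" , unary | pow ;
pow          = atom , [ "^" , unary ] ;
atom         = NUMBER | NAME | "(" , arith , ")" ;

NAME         = ? [A-Za-z_][A-Za-z0-9_]* ? ;
NUMBER       = ? [0-9]+(\.[0-9]+)?([eE][+-]?[0-9]+)? ? ;
```

## Notes

- A gate attaches to the single action after `->`; the gated action takes
  part in choice normally and is simply disabled while the condition is
  false.
- A channel component that is a bare identifier evaluates to its numeric
  value when the name is bound (parameter, binding variable or constant)
  and otherwise stays a symbolic name. Symbolic and numeric channel
  components never match each other.
- Set subtraction `\` is an operator, never an escape character.
- Number literals have no sign; negative values are written with unary
  minus, e.g. `B[-5]`.
- A parenthesised term may only appear as the last element of a prefix
  chain (a general term cannot prefix an action).
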