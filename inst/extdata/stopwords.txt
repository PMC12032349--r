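the
and
for
with
from
into
that
this
are
was
were
has
have
had
not
but
all
any
can
may
via
per
one
two
its
their
other
related
putative
predicted
hypothetical
conserved
domain
protein
proteins
family
subunit
type
like
containing
associated
dependent
specific
system
component
chain
large
small
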